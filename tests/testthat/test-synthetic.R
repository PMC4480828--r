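test_that("generateGenome places disjoint genes deterministically", {
  sizes <- c(chr1 = 100000)
  gm <- generateGenome(sizes, nGenes = 5, seed = 1)
  genes <- gm[gm$type == "gene"]
  expect_equal(length(genes), 5L)
  expect_true(all(start(genes) >= 1 & end(genes) <= 100000))
  expect_true(isDisjoint(granges(genes), ignore.strand = TRUE))

  gm2 <- generateGenome(sizes, nGenes = 5, seed = 1)
  expect_identical(gm, gm2)

  ## 50 genes on 1 Mb: pairwise disjointness at scale
  big <- generateGenome(c(chr1 = 1e6), nGenes = 50, seed = 2)
  expect_true(isDisjoint(granges(big[big$type == "gene"]),
                         ignore.strand = TRUE))
  ## exons stay inside their gene and the CDS inside the exons
  for (gid in unique(big$gene_id)[1:5]) {
    g <- big[big$gene_id == gid]
    span <- g[g$type == "gene"]
    ex <- g[g$type == "exon"]
    cd <- g[g$type == "CDS"]
    expect_true(all(start(ex) >= start(span) & end(ex) <= end(span)))
    expect_equal(sum(width(setdiff(reduce(granges(cd), ignore.strand = TRUE),
                                   reduce(granges(ex), ignore.strand = TRUE)))), 0)
  }

  expect_error(generateGenome(c(chr1 = 1000), nGenes = 50, seed = 1),
               "cannot fit")
})

test_that("generateTrack hits its target coverage and is reproducible", {
  sizes <- c(chr1 = 700000, chr2 = 300000)
  tr <- generateTrack("t", 0.01, 300, sizes, seed = 3)
  expect_lt(abs(trackLength(tr) - 10000), 500)
  tr2 <- generateTrack("t", 0.01, 300, sizes, seed = 3)
  expect_identical(trackRanges(tr), trackRanges(tr2))

  dense <- generateTrack("d", 0.9, 2000, c(chr1 = 100000), seed = 4)
  expect_lt(abs(trackLength(dense) - 90000), 4500)

  expect_error(generateTrack("x", 1.5, 300, sizes), "infeasible")

  ## independently seeded tracks overlap like independent random sets;
  ## the sampling unit is the interval, not the base pair, so the 3-SD
  ## band uses the interval counts of the two tracks
  a <- generateTrack("a", 0.2, 500, c(chr1 = 500000), seed = 5)
  b <- generateTrack("b", 0.3, 500, c(chr1 = 500000), seed = 6)
  expected <- 0.2 * 0.3 * 500000
  relSd <- sqrt(1 / length(a) + 1 / length(b))
  expect_lt(abs(overlapLength(a, b) - expected), 3 * relSd * expected)
})

test_that("generatePool draws unique keys with the configured AF spectrum", {
  sizes <- c(chr1 = 1000)
  pool <- generatePool(10, sizes, seed = 7)
  expect_equal(length(pool), 10L)
  expect_equal(anyDuplicated(variantKeys(pool)), 0L)
  expect_identical(variantKeys(generatePool(10, sizes, seed = 7)),
                   variantKeys(pool))

  ## chi-squared goodness of fit of 10,000 Beta(0.2, 2) draws
  big <- generatePool(10000, c(chr1 = 5e6), seed = 8)
  af <- alleleFreqs(big)
  edges <- c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5, 1)
  obs <- table(cut(af, edges, include.lowest = TRUE))
  p <- diff(pbeta(edges, 0.2, 2))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("plantDiseaseSet places variants at the calibrated probability", {
  expect_equal(plantPlacementProb(1, 0.37), 0.37)   # null case
  expect_equal(round(plantPlacementProb(5, 0.01), 5), 0.04808)

  ## analytic identity: placement odds over coverage odds equal lambda
  set.seed(201)
  for (i in 1:20) {
    lam <- runif(1, 0.5, 30)
    cov <- runif(1, 0.001, 0.5)
    p <- plantPlacementProb(lam, cov)
    expect_equal((p / (1 - p)) / (cov / (1 - cov)), lam, tolerance = 1e-12)
  }

  sizes <- c(chr1 = 1e6)
  track <- generateTrack("t", 0.01, 300, sizes, seed = 9)
  cov <- trackLength(track) / 1e6
  set <- plantDiseaseSet("d", 10000, track, sizes, lambda = 5, seed = 10)
  inFrac <- countVariantsInTrack(set, track) / 10000
  p <- plantPlacementProb(5, cov)
  expect_lt(abs(inFrac - p), 3 * sqrt(p * (1 - p) / 10000))

  expect_identical(
    variantKeys(plantDiseaseSet("d", 100, track, sizes, 5, seed = 11)),
    variantKeys(plantDiseaseSet("d", 100, track, sizes, 5, seed = 11)))
})

test_that("simulateScenario wires components together reproducibly", {
  cfg <- smallScenarioConfig(seed = 21)
  sc <- simulateScenario(cfg)
  expect_named(sc$tracks, c("promoter", "enhancer"))
  expect_named(sc$diseaseSets, c("mendelian", "complex"))
  expect_equal(length(sc$diseaseSets$mendelian), 800L)
  ## background excludes every disease key
  expect_length(intersect(variantKeys(sc$background),
                          variantKeys(sc$diseaseSets$mendelian)), 0)
  ## coding flags agree with the partition's coding-exon class
  vs <- sc$diseaseSets$mendelian
  expect_equal(sum(mcols(variantRanges(vs))$coding),
               countVariantsInTrack(vs, partitionTrack(sc$partition, "coding_exon")))

  sc2 <- simulateScenario(smallScenarioConfig(seed = 21))
  expect_identical(variantKeys(sc$pool), variantKeys(sc2$pool))
  expect_identical(trackRanges(sc$tracks$promoter),
                   trackRanges(sc2$tracks$promoter))

  badCfg <- smallScenarioConfig()
  badCfg$diseaseSpecs[[1]]$track <- "nope"
  expect_error(simulateScenario(badCfg), "unknown track")
})
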