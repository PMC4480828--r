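test_that("afHistogram bins every variant exactly once", {
  vs <- VariantSet("x", rep("chr1", 3), 1:3, "A", "G",
                   af = c(0.01, 0.2, 0.2))
  h <- afHistogram(vs, edges = c(0, 0.1, 0.5))
  expect_equal(unname(histCounts(h)), c(1, 2, 0))

  allMissing <- VariantSet("m", rep("chr1", 5), 1:5, "A", "G")
  hm <- afHistogram(allMissing)
  expect_equal(unname(histCounts(hm)[["missing"]]), 5)
  expect_equal(sum(histCounts(hm)), 5)

  ## 500 random AFs against a brute-force binning oracle
  set.seed(121)
  af <- c(runif(450), rep(NA, 50))
  vs2 <- VariantSet("r", rep("chr1", 500), 1:500, "A", "G", af = af)
  edges <- defaultAfBinEdges()
  h2 <- afHistogram(vs2, edges)
  oracle <- vapply(seq_len(length(edges) - 1), function(i) {
    hi <- if (i == length(edges) - 1) af <= edges[i + 1] else af < edges[i + 1]
    sum(!is.na(af) & af >= edges[i] & hi)
  }, 0)
  expect_equal(unname(histCounts(h2)), c(oracle, 50))
  expect_error(afHistogram(vs2, edges = c(0, 0.5, 0.5, 1)),
               "strictly increasing")
})

test_that("matched control sets reproduce the target histogram exactly", {
  sizes <- c(chr1 = 100000)
  set.seed(131)
  disease <- variantSetFromTable("d", randomVariantTable(131, 200, sizes),
                                 af = c(rbeta(180, 0.2, 2), rep(NA, 20)))
  pool <- variantSetFromTable("p", randomVariantTable(132, 4000, sizes),
                              af = c(rbeta(3800, 0.2, 2), rep(NA, 200)))
  target <- afHistogram(disease)
  for (seed in c(1, 7, 99)) {
    sets <- sampleMatchedControls(pool, disease, nSets = 3, seed = seed)
    for (s in sets) {
      expect_equal(length(s), length(disease))
      expect_identical(histCounts(afHistogram(s)), histCounts(target))
    }
  }
})

test_that("matched sampling is seed-reproducible and seed-sensitive", {
  sizes <- c(chr1 = 50000)
  disease <- variantSetFromTable("d", randomVariantTable(141, 100, sizes),
                                 af = rbeta(100, 0.2, 2))
  pool <- variantSetFromTable("p", randomVariantTable(142, 2000, sizes),
                              af = rbeta(2000, 0.2, 2))
  a <- sampleMatchedControls(pool, disease, nSets = 4, seed = 5)
  b <- sampleMatchedControls(pool, disease, nSets = 4, seed = 5)
  expect_identical(lapply(a, variantKeys), lapply(b, variantKeys))
  c2 <- sampleMatchedControls(pool, disease, nSets = 4, seed = 6)
  expect_false(identical(lapply(a, variantKeys), lapply(c2, variantKeys)))

  ## forced selection: pool bin exactly equals the quota
  dOne <- VariantSet("d", rep("chr1", 5), 1:5, "A", "G", af = rep(0.02, 5))
  pOne <- VariantSet("p", rep("chr1", 5), 11:15, "A", "G",
                     af = rep(0.03, 5))
  forced <- sampleMatchedControls(pOne, dOne, nSets = 2, seed = 1)
  expect_setequal(variantKeys(forced[[1]]), variantKeys(pOne))

  ## capacity error names the failing bin and the shortfall
  tiny <- VariantSet("p", rep("chr1", 3), 21:23, "A", "G", af = rep(0.02, 3))
  expect_error(sampleMatchedControls(tiny, dOne, nSets = 1, seed = 1),
               "bin \\[0.01,0.05\\).*shortfall 2")
})

test_that("qValueSummary applies BH step-up over replicate p-values", {
  expect_equal(qValueSummary(rep(0.001, 1000)), 0.001)
  expect_equal(qValueSummary(c(0.01, 0.02, 0.03, 0.04)), 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(qValueSummary(rep(1, 10)), 1)
  expect_error(qValueSummary(numeric()), "empty")
  expect_error(qValueSummary(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("matchedEnrichment is deterministic and consistent with the sampler", {
  sizes <- c(chr1 = 200000)
  track <- generateTrack("t", 0.02, 300, sizes, seed = 151)
  disease <- plantDiseaseSet("d", 300, track, sizes, lambda = 4, seed = 152)
  pool <- generatePool(5000, sizes, seed = 153)
  bg <- subtractVariants(pool, disease)

  r1 <- matchedEnrichment(disease, bg, track, nSets = 30, seed = 9)
  r2 <- matchedEnrichment(disease, bg, track, nSets = 30, seed = 9)
  expect_identical(replicateORs(r1), replicateORs(r2))
  expect_identical(replicatePs(r1), replicatePs(r2))
  expect_equal(medianOR(r1), median(replicateORs(r1)[is.finite(replicateORs(r1))]))
  expect_equal(r1@significantFraction, mean(replicatePs(r1) < 0.05))

  ## replicate i of the sampler stream gives the same control set
  sets <- sampleMatchedControls(bg, disease, nSets = 3, seed = 9)
  or3 <- oddsRatio(buildContingencyTable(disease, sets[[3]], track))
  expect_equal(replicateORs(r1)[3], or3)

  ## disease keys drawn from the pool itself must be rejected
  overlapping <- subsetVariants(pool, 1:50, label = "overlap")
  expect_error(matchedEnrichment(overlapping, pool, track, nSets = 5,
                                 seed = 1),
               "share")
})

test_that("a track covering the whole genome yields flagged replicates", {
  sizes <- c(chr1 = 50000)
  whole <- mergeTrack(GRanges("chr1", IRanges(1, 50000)), "whole")
  disease <- variantSetFromTable("d", randomVariantTable(161, 50, sizes),
                                 af = rbeta(50, 0.2, 2))
  pool <- subtractVariants(
    variantSetFromTable("p", randomVariantTable(162, 1000, sizes),
                        af = rbeta(1000, 0.2, 2)), disease)
  expect_warning(res <- matchedEnrichment(disease, pool, whole, nSets = 10,
                                          seed = 3),
                 "zero-margin")
  expect_equal(res@nNonFinite, 10L)
  expect_true(is.na(medianOR(res)))
  expect_equal(qSummary(res), 1)
})

test_that("the null (lambda = 1) keeps its nominal test size", {
  sizes <- c(chr1 = 1500000)
  track <- generateTrack("t", 0.01, 300, sizes, seed = 171)
  disease <- plantDiseaseSet("null", 2000, track, sizes, lambda = 1,
                             seed = 172)
  pool <- generatePool(30000, sizes, seed = 173)
  bg <- subtractVariants(pool, disease)
  res <- matchedEnrichment(disease, bg, track, nSets = 200, seed = 174)
  ## size of the test: within 3 binomial SDs of alpha at 200 replicates
  band <- 3 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(res@significantFraction - 0.05), band)
  ## and the median OR sits near 1
  expect_gt(medianOR(res), 0.75)
  expect_lt(medianOR(res), 1.3)
})
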