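test_that("buildContingencyTable counts within/outside and checks disjointness", {
  sizes <- c(chr1 = 20000)
  track <- mergeTrack(GRanges("chr1", IRanges(1000, 2000)), "t")
  inside <- VariantSet("d", rep("chr1", 10), 1000:1009, "A", "G")
  outside <- VariantSet("c", rep("chr1", 10), 5000:5009, "A", "G")
  t <- buildContingencyTable(inside, outside, track)
  expect_equal(unname(tableCells(t)), c(10, 0, 0, 10))

  empty <- mergeTrack(GRanges(), "empty")
  t2 <- buildContingencyTable(inside, outside, empty)
  expect_equal(unname(tableCells(t2)), c(0, 10, 0, 10))

  ## margins always add to the set sizes on random fixtures
  d <- variantSetFromTable("d", randomVariantTable(91, 80, sizes))
  cOnly <- subtractVariants(
    variantSetFromTable("c", randomVariantTable(92, 120, sizes)), d)
  tr <- mergeTrack(randomIntervals(93, 20, sizes, 500), "r")
  t3 <- buildContingencyTable(d, cOnly, tr)
  cells <- tableCells(t3)
  expect_equal(unname(cells["dmw"] + cells["dmo"]), length(d))
  expect_equal(unname(cells["dcw"] + cells["dco"]), length(cOnly))
  bp <- oracleTrackBpSet(tr)
  expect_equal(unname(cells["dmw"]),
               sum(sub(":[ACGT]+:[ACGT]+$", "", variantKeys(d)) %in% bp))

  expect_error(buildContingencyTable(d, d, tr), "share")
})

test_that("oddsRatio handles plain, zero-cell and corrected cases", {
  expect_equal(oddsRatio(ContingencyTable2x2(5, 95, 5, 95)), 1)
  expect_equal(oddsRatio(ContingencyTable2x2(10, 90, 5, 95)),
               (10 / 90) / (5 / 95))
  expect_equal(round(oddsRatio(ContingencyTable2x2(10, 90, 5, 95)), 4), 2.1111)
  expect_equal(oddsRatio(ContingencyTable2x2(0, 10, 5, 95)), 0)
  ## zero in a denominator cell flags the result rather than altering it
  expect_true(is.infinite(oddsRatio(ContingencyTable2x2(5, 0, 5, 95))))
  expect_true(is.nan(oddsRatio(ContingencyTable2x2(0, 10, 0, 95))))
  ## Haldane-Anscombe correction only when requested
  expect_equal(oddsRatio(ContingencyTable2x2(0, 10, 5, 95), zeroCell = "haldane"),
               (0.5 / 10.5) / (5.5 / 95.5))
})

test_that("log odds ratio and SE reproduce printed and hand-computed values", {
  ## printed fold-enrichments and their printed log values
  expect_equal(round(log(21), 2), 3.04)
  t21 <- ContingencyTable2x2(21, 1, 1, 1)
  expect_equal(round(logOrSe(t21)[["log_or"]], 2), 3.04)
  expect_equal(round(logOrSe(ContingencyTable2x2(1057, 100, 100, 100))[["log_or"]], 2),
               2.36)
  expect_equal(round(logOrSe(ContingencyTable2x2(19, 10, 10, 10))[["log_or"]], 2),
               0.64)

  expect_equal(logOrSe(ContingencyTable2x2(1, 1, 1, 1))[["se"]], 2)
  expect_equal(round(logOrSe(ContingencyTable2x2(10, 90, 5, 95))[["se"]], 4),
               0.5671)
  expect_equal(logOrSe(ContingencyTable2x2(10, 90, 5, 95))[["se"]],
               sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95))
})

test_that("pearsonChi2 matches hand-computed expecteds and the closed form", {
  ind <- pearsonChi2(ContingencyTable2x2(5, 95, 5, 95))
  expect_equal(unname(ind), c(0, 1))

  got <- pearsonChi2(ContingencyTable2x2(10, 90, 5, 95))
  expect_equal(round(got[["statistic"]], 4), 1.8018)

  ## 1000 random tables: statistic equals N(ad-bc)^2/(r1 r2 c1 c2) to 1e-9
  set.seed(101)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(c(2, 10, 40), 1)) + 1
    t <- ContingencyTable2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(pearsonChi2(t)[["statistic"]],
                 oracleChi2Closed(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }

  ## independent cross-check against stats::chisq.test (no correction)
  set.seed(102)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    t <- ContingencyTable2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(
      stats::chisq.test(matrix(cells[c(1, 3, 2, 4)], 2), correct = FALSE))
    expect_equal(pearsonChi2(t)[["statistic"]], unname(ref$statistic))
    expect_equal(pearsonChi2(t)[["p"]], unname(ref$p.value))
  }

  expect_warning(res <- pearsonChi2(ContingencyTable2x2(0, 0, 5, 95)),
                 "zero margin")
  expect_equal(unname(res), c(0, 1))
})

test_that("odds ratio and chi-squared algebraic invariances hold", {
  set.seed(103)
  for (i in 1:50) {
    cells <- rpois(4, 15) + 1
    t <- ContingencyTable2x2(cells[1], cells[2], cells[3], cells[4])
    swapped <- ContingencyTable2x2(cells[3], cells[4], cells[1], cells[2])
    expect_equal(oddsRatio(t) * oddsRatio(swapped), 1)
    k <- sample(2:5, 1)
    scaled <- ContingencyTable2x2(k * cells[1], k * cells[2],
                                  k * cells[3], k * cells[4])
    expect_equal(oddsRatio(scaled), oddsRatio(t))
    expect_equal(pearsonChi2(scaled)[["statistic"]],
                 k * pearsonChi2(t)[["statistic"]], tolerance = 1e-9)
  }
})

test_that("enrichmentTable emits one labelled row per pair", {
  sizes <- c(chr1 = 30000)
  d <- variantSetFromTable("mendelian", randomVariantTable(111, 60, sizes))
  bg <- subtractVariants(
    variantSetFromTable("background", randomVariantTable(112, 400, sizes)), d)
  tracks <- list(mergeTrack(randomIntervals(113, 10, sizes, 400), "a"),
                 mergeTrack(randomIntervals(114, 10, sizes, 400), "b"))
  et <- enrichmentTable(list(d), bg, tracks)
  expect_equal(nrow(et), 2L)
  expect_equal(et$category, rep("mendelian", 2))
  expect_equal(et$track, c("a", "b"))
  expect_equal(et$dmw + et$dmo, rep(length(d), 2))
  expect_equal(et$log_or, log(et$odds_ratio))
})
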