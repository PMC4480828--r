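test_that("mergeTrack unions overlapping, abutting and duplicate intervals", {
  gr <- GRanges("chr1", IRanges(c(1, 51), c(100, 150)))
  tr <- mergeTrack(gr, "t")
  expect_equal(length(tr), 1L)
  expect_equal(trackLength(tr), 150)

  ## abutting intervals merge (zero gap contributes nothing to the union)
  ab <- mergeTrack(GRanges("chr1", IRanges(c(11, 21), c(20, 30))))
  expect_equal(length(ab), 1L)
  expect_equal(start(trackRanges(ab)), 11)
  expect_equal(end(trackRanges(ab)), 30)

  dup <- mergeTrack(rep(GRanges("chr1", IRanges(1, 10)), 3))
  expect_equal(trackLength(dup), 10)

  empty <- mergeTrack(GRanges())
  expect_equal(trackLength(empty), 0)

  two <- mergeTrack(GRanges(c("chr1", "chr2"), IRanges(1, 100)))
  expect_equal(trackLength(two), 200)
})

test_that("merge is idempotent and matches the per-bp union oracle", {
  chromSizes <- c(chrA = 10000)
  for (seed in 1:5) {
    raw <- randomIntervals(seed, 100, chromSizes, maxLen = 300)
    tr <- mergeTrack(raw, "rand")
    expect_equal(trackLength(tr), length(unique(oracleBpSetGr(raw))))
    remerged <- mergeTrack(trackRanges(tr), "rand")
    expect_identical(trackRanges(remerged), trackRanges(tr))
  }
})

test_that("overlapLength is symmetric, self-consistent and oracle-exact", {
  a <- mergeTrack(GRanges("chr1", IRanges(1, 100)), "a")
  b <- mergeTrack(GRanges("chr1", IRanges(51, 150)), "b")
  expect_equal(overlapLength(a, b), 50)
  disjoint <- mergeTrack(GRanges("chr2", IRanges(1, 100)), "d")
  expect_equal(overlapLength(a, disjoint), 0)

  chromSizes <- c(chrA = 10000)
  for (seed in 6:10) {
    x <- mergeTrack(randomIntervals(seed, 10, chromSizes, 800), "x")
    y <- mergeTrack(randomIntervals(seed + 100, 10, chromSizes, 800), "y")
    expect_equal(overlapLength(x, y), overlapLength(y, x))
    expect_equal(overlapLength(x, x), trackLength(x))
    expect_equal(overlapLength(x, y),
                 length(intersect(oracleTrackBpSet(x), oracleTrackBpSet(y))))
  }
})

test_that("readBed merges records and rejects malformed input", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\t150"), bed)
  tr <- readBed(bed)
  expect_equal(trackLength(tr), 150)
  expect_equal(length(tr), 1L)

  writeLines(c("chr1\t0\t100", "chr2\t0\t100"), bed)
  expect_equal(trackLength(readBed(bed)), 200)

  ## abutting BED records union into one interval
  writeLines(c("chr1\t10\t20", "chr1\t20\t30"), bed)
  tr <- readBed(bed)
  expect_equal(length(tr), 1L)
  expect_equal(trackLength(tr),
               length(unique(oracleBpSet(c("chr1", "chr1"), c(11, 21), c(20, 30)))))

  writeLines(c("chr1\t0\t100", "chr1\txx\t200"), bed)
  expect_error(readBed(bed), "line 2")
  writeLines(c("chr1\t0\t100", "chr1\t200\t200"), bed)
  expect_error(readBed(bed), "line 2")
  writeLines("chr1\t5", bed)
  expect_error(readBed(bed), "3 columns")

  ## chrom normalization and comment/track-line skipping
  writeLines(c("# a comment", "track name=x", "1\t0\t10"), bed)
  expect_equal(as.character(seqnames(trackRanges(readBed(bed)))), "chr1")
})

test_that("tracks round-trip through BED", {
  chromSizes <- c(chrA = 10000)
  tr <- mergeTrack(randomIntervals(42, 30, chromSizes, 400), "rt")
  bed <- tempfile(fileext = ".bed")
  writeBedTrack(tr, bed)
  back <- readBed(bed, label = "rt", chromPrefix = FALSE)
  expect_identical(ranges(trackRanges(back)), ranges(trackRanges(tr)))
})

test_that("percentOverlap reproduces printed worked examples", {
  expect_equal(percentOverlap(318864, 3833500), 8.32)
  expect_equal(percentOverlap(0, 12345), 0)
  expect_equal(percentOverlap(275, 12385403, digits = 3), 0.002)
  expect_error(percentOverlap(10, 0), "zero track length")
})

test_that("genome partition handles flank clipping at chromosome bounds", {
  ## one + strand gene near the chromosome start: upstream flank clipped
  gm <- GRanges("chr1", IRanges(c(1001, 1001, 1201), c(2000, 2000, 1800)),
                strand = "+", type = c("gene", "exon", "CDS"),
                gene_id = "g1")
  part <- buildGenomePartition(gm, c(chr1 = 10000), flank = 2000)
  up <- trackRanges(partitionTrack(part, "upstream"))
  expect_equal(start(up), 1)
  expect_equal(end(up), 1000)
  down <- trackRanges(partitionTrack(part, "downstream"))
  expect_equal(start(down), 2001)
  expect_equal(end(down), 4000)
  ig <- trackRanges(partitionTrack(part, "intergenic"))
  expect_equal(start(ig), 4001)
  expect_equal(end(ig), 10000)
  expect_equal(trackLength(partitionTrack(part, "utr5")), 200)
  expect_equal(trackLength(partitionTrack(part, "utr3")), 200)

  ## gene spanning the whole chromosome leaves no intergenic space
  whole <- GRanges("chr1", IRanges(c(1, 1, 2), c(5000, 5000, 4999)),
                   strand = "+", type = c("gene", "exon", "CDS"),
                   gene_id = "g1")
  partWhole <- buildGenomePartition(whole, c(chr1 = 5000))
  expect_equal(trackLength(partitionTrack(partWhole, "intergenic")), 0)
})

test_that("partition classes match the brute-force per-bp classifier", {
  ## two overlapping genes on opposite strands, multi-exon, hand-built
  gm <- c(
    GRanges("chr1", IRanges(c(3000, 3000, 4200, 3400, 4200),
                            c(5000, 3800, 5000, 3800, 4600)),
            strand = "+",
            type = c("gene", "exon", "exon", "CDS", "CDS"),
            gene_id = "gA"),
    GRanges("chr1", IRanges(c(4500, 4500, 6200, 4800, 6200),
                            c(7000, 5600, 7000, 5600, 6800)),
            strand = "-",
            type = c("gene", "exon", "exon", "CDS", "CDS"),
            gene_id = "gB"))
  chromSizes <- c(chr1 = 12000)
  part <- buildGenomePartition(gm, chromSizes, flank = 2000)
  oracle <- oracleClassifyGenome(geneModelsToDf(gm), chromSizes, flank = 2000)
  for (cl in names(oracle)) {
    got <- sort(oracleTrackBpSet(partitionTrack(part, cl)))
    expect_equal(got, sort(oracle[[cl]]), label = paste("class", cl))
  }
})

test_that("partition of a generated genome is oracle-exact and covers it", {
  chromSizes <- c(chr1 = 30000, chr2 = 20000)
  gm <- generateGenome(chromSizes, nGenes = 10, seed = 5)
  part <- buildGenomePartition(gm, chromSizes, flank = 2000)
  oracle <- oracleClassifyGenome(geneModelsToDf(gm), chromSizes, flank = 2000)
  for (cl in names(oracle)) {
    got <- sort(oracleTrackBpSet(partitionTrack(part, cl)))
    expect_equal(got, sort(oracle[[cl]]), label = paste("class", cl))
  }
  ## the seven classes jointly cover every base of the toy genome
  covered <- Reduce(union, lapply(partitionClasses(part), function(cl)
    oracleTrackBpSet(partitionTrack(part, cl))))
  expect_equal(length(covered), sum(chromSizes))
})

test_that("unstranded genes default to + strand with a warning", {
  gm <- GRanges("chr1", IRanges(c(5000, 5000, 5100), c(6000, 6000, 5900)),
                strand = "*", type = c("gene", "exon", "CDS"), gene_id = "g1")
  expect_warning(part <- buildGenomePartition(gm, c(chr1 = 20000)),
                 "unstranded")
  up <- trackRanges(partitionTrack(part, "upstream"))
  expect_equal(c(start(up), end(up)), c(3000, 4999))
})
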