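## Independent brute-force oracles: per-bp set arithmetic and linear scans
## on toy genomes, implemented with base R only so they share no code with
## the interval layer they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Encode each covered base of a GRanges-like (chrom, start, end) table as
## "chrom:pos" strings. Feasible for toy genomes (<= 100 kb).
oracleBpSet <- function(chrom, start, end) {
  if (!length(chrom)) return(character())
  unlist(Map(function(c, s, e) paste0(c, ":", s:e), chrom, start, end),
         use.names = FALSE)
}

oracleBpSetGr <- function(gr) {
  oracleBpSet(as.character(seqnames(gr)), start(gr), end(gr))
}

oracleTrackBpSet <- function(track) oracleBpSetGr(trackRanges(track))

## Random raw (unmerged) intervals on a toy genome; plain base R.
randomIntervals <- function(seed, n, chromSizes, maxLen = 500) {
  set.seed(seed)
  chrom <- sample(names(chromSizes), n, replace = TRUE)
  start <- vapply(chrom, function(c) sample.int(chromSizes[[c]], 1L), 0L)
  len <- sample.int(maxLen, n, replace = TRUE)
  end <- pmin(start + len - 1, chromSizes[chrom])
  GRanges(chrom, IRanges(start, end))
}

## Random point variants; returns the plain coordinate table.
randomVariantTable <- function(seed, n, chromSizes) {
  set.seed(seed)
  chrom <- sample(names(chromSizes), n, replace = TRUE)
  pos <- vapply(chrom, function(c) sample.int(chromSizes[[c]], 1L), 0L)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

variantSetFromTable <- function(label, df, ...) {
  suppressMessages(VariantSet(label, df$chrom, df$pos, df$ref, df$alt, ...,
                              chromPrefix = FALSE))
}

## Closed-form Pearson chi-squared for a 2x2 table: N(ad-bc)^2/(r1 r2 c1 c2).
oracleChi2Closed <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

## Brute-force per-bp classifier for the seven genomic classes, computed
## from first principles (per-gene loops over integer position vectors).
oracleClassifyGenome <- function(geneDf, chromSizes, flank = 2000) {
  ## geneDf: one row per gene with chrom, start, end, strand and list
  ## columns exons / cds of (start, end) matrices
  classes <- list(coding_exon = character(), utr5 = character(),
                  utr3 = character(), intron = character(),
                  upstream = character(), downstream = character())
  footprint <- character()
  bp <- function(chrom, s, e, size) {
    s <- max(1, s); e <- min(size, e)
    if (s > e) return(character())
    paste0(chrom, ":", s:e)
  }
  for (i in seq_len(nrow(geneDf))) {
    g <- geneDf[i, ]
    size <- chromSizes[[g$chrom]]
    span <- bp(g$chrom, g$start, g$end, size)
    exonPos <- unlist(lapply(seq_len(nrow(g$exons[[1]])), function(j)
      bp(g$chrom, g$exons[[1]][j, 1], g$exons[[1]][j, 2], size)))
    cdsPos <- if (is.null(g$cds[[1]])) character() else
      unlist(lapply(seq_len(nrow(g$cds[[1]])), function(j)
        bp(g$chrom, g$cds[[1]][j, 1], g$cds[[1]][j, 2], size)))
    if (g$strand == "+") {
      up <- bp(g$chrom, g$start - flank, g$start - 1, size)
      down <- bp(g$chrom, g$end + 1, g$end + flank, size)
    } else {
      up <- bp(g$chrom, g$end + 1, g$end + flank, size)
      down <- bp(g$chrom, g$start - flank, g$start - 1, size)
    }
    classes$intron <- union(classes$intron, setdiff(span, exonPos))
    classes$coding_exon <- union(classes$coding_exon, cdsPos)
    classes$upstream <- union(classes$upstream, up)
    classes$downstream <- union(classes$downstream, down)
    if (length(cdsPos)) {
      cdsStartEnd <- range(g$cds[[1]])
      exonStarts <- as.integer(sub(".*:", "", exonPos))
      left <- exonPos[exonStarts < min(g$cds[[1]])]
      right <- exonPos[exonStarts > max(g$cds[[1]])]
      if (g$strand == "+") {
        classes$utr5 <- union(classes$utr5, left)
        classes$utr3 <- union(classes$utr3, right)
      } else {
        classes$utr5 <- union(classes$utr5, right)
        classes$utr3 <- union(classes$utr3, left)
      }
    }
    footprint <- union(footprint, c(span, up, down))
  }
  all <- unlist(lapply(names(chromSizes), function(c)
    paste0(c, ":", seq_len(chromSizes[[c]]))))
  classes$intergenic <- setdiff(all, footprint)
  classes
}

## Convert generator gene models (GRanges with type/gene_id) into the
## classifier's per-gene table.
geneModelsToDf <- function(gm) {
  genes <- gm[gm$type == "gene"]
  rows <- lapply(seq_along(genes), function(i) {
    gid <- genes$gene_id[i]
    ex <- gm[gm$type == "exon" & gm$gene_id == gid]
    cd <- gm[gm$type == "CDS" & gm$gene_id == gid]
    data.frame(chrom = as.character(seqnames(genes[i])),
               start = start(genes[i]), end = end(genes[i]),
               strand = as.character(strand(genes[i])),
               exons = I(list(cbind(start(ex), end(ex)))),
               cds = I(list(if (length(cd)) cbind(start(cd), end(cd)) else NULL)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Small scenario used by pipeline-level tests (kept light: half-megabase
## genome, modest pool).
smallScenarioConfig <- function(seed = 11) {
  cfg <- syntheticConfig(seed)
  cfg$chromSizes <- c(chr1 = 4e5, chr2 = 2e5)
  cfg$nGenes <- 40
  cfg$poolSize <- 8000
  cfg$trackSpecs <- list(
    list(label = "promoter", fraction = 0.01, meanLength = 300),
    list(label = "enhancer", fraction = 0.03, meanLength = 400))
  cfg$diseaseSpecs <- list(
    list(category = "mendelian", n = 800, track = "promoter", lambda = 20),
    list(category = "complex", n = 600, track = "enhancer", lambda = 1.5))
  cfg
}
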