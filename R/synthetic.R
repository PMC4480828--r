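## Synthetic-data module: toy genomes, gene models, regulatory tracks,
## background pools and disease sets with planted fold-enrichment. Every
## generator is reproducible from (config, seed).

#' Sample allele frequencies from a configurable model
#'
#' @param n number of draws.
#' @param model list with `dist` (`"beta"`, `"uniform"` or `"fixed"`) and
#'   its parameters; the optional `missing` entry gives the fraction of
#'   draws set to `NA` (a missing-AF stratum). The default Beta(0.2, 2) is
#'   rare-skewed, resembling site-frequency spectra.
#' @return Numeric vector of frequencies in `[0, 1]` (with `NA`s when
#'   `missing > 0`).
#' @export
sampleAf <- function(n, model = defaultAfModel()) {
  af <- switch(model$dist,
    beta = rbeta(n, model$shape1, model$shape2),
    uniform = runif(n, model$min %||% 0, model$max %||% 1),
    fixed = rep(model$value, n),
    stop("unknown AF model '", model$dist, "'"))
  miss <- model$missing %||% 0
  if (miss > 0) af[runif(n) < miss] <- NA_real_
  af
}

#' @rdname sampleAf
#' @export
defaultAfModel <- function() list(dist = "beta", shape1 = 0.2, shape2 = 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

## k positions uniform over the bases covered by gr (1-based, within-range).
.samplePositionsInRanges <- function(gr, k) {
  if (k == 0L) return(GRanges())
  total <- sum(width(gr))
  stopifnot(total > 0)
  u <- pmax(1, ceiling(runif(k) * total))
  cum <- cumsum(width(gr))
  idx <- findInterval(u - 0.5, c(0, cum))
  pos <- start(gr)[idx] + (u - c(0, cum)[idx] - 1)
  GRanges(seqnames(gr)[idx], IRanges(pos, width = 1L))
}

.randomAlleles <- function(k) {
  refI <- sample.int(4L, k, replace = TRUE)
  altI <- ((refI - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L
  list(ref = .BASES[refI], alt = .BASES[altI])
}

#' Generate a toy genome annotation
#'
#' Places `nGenes` non-overlapping genes across the chromosomes
#' (proportional to chromosome size), each with 1-4 exons and a CDS leaving
#' UTRs at both ends, on a random strand. Deterministic under `seed`.
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param nGenes total gene count.
#' @param seed integer seed.
#' @return `GRanges` gene models (`type` in gene/exon/CDS, `gene_id`), as
#'   consumed by [buildGenomePartition].
#' @export
generateGenome <- function(chromSizes, nGenes, seed = 1) {
  stopifnot(nGenes > 0, all(chromSizes > 0))
  withSeed(seed, {
    share <- chromSizes / sum(chromSizes)
    nPer <- floor(share * nGenes)
    rem <- nGenes - sum(nPer)
    if (rem > 0) {
      ord <- order(share * nGenes - nPer, decreasing = TRUE)
      nPer[ord[seq_len(rem)]] <- nPer[ord[seq_len(rem)]] + 1L
    }
    rows <- list()
    for (chrom in names(chromSizes)) {
      nc <- nPer[[chrom]]
      if (nc == 0L) next
      slot <- floor(chromSizes[[chrom]] / nc)
      if (slot < 400L)
        stop("genes cannot fit: ", nc, " genes on ", chrom, " of ",
             chromSizes[[chrom]], " bp leaves ", slot, " bp per gene")
      for (i in seq_len(nc)) {
        slotStart <- (i - 1L) * slot      # 0-based slot origin
        geneLen <- max(200L, min(slot - 2L, round(runif(1, 0.3, 0.7) * slot)))
        gs <- slotStart + sample.int(slot - geneLen, 1L)  # 1-based start
        rows[[length(rows) + 1L]] <-
          .buildGene(chrom, gs, gs + geneLen - 1L,
                     strand = sample(c("+", "-"), 1L),
                     geneId = sprintf("%s_g%04d", chrom, i))
      }
    }
    rows <- lapply(rows, function(r) {
      seqlevels(r) <- names(chromSizes)
      r
    })
    gm <- do.call(c, rows)
    seqinfo(gm) <- Seqinfo(names(chromSizes),
                           seqlengths = unname(chromSizes))
    gm
  })
}

## One gene with alternating exon/intron segments and an interior CDS.
.buildGene <- function(chrom, gs, ge, strand, geneId) {
  w <- ge - gs + 1L
  nEx <- max(1L, sample.int(min(4L, max(1L, w %/% 150L)), 1L))
  nSeg <- 2L * nEx - 1L
  props <- runif(nSeg, 0.5, 1.5)
  segLen <- pmax(20L, floor(props / sum(props) * w))
  segLen[nSeg] <- w - sum(segLen[-nSeg])
  stopifnot(segLen[nSeg] >= 1L)
  bounds <- gs + c(0L, cumsum(segLen))
  exI <- seq(1L, nSeg, by = 2L)
  exStart <- bounds[exI]
  exEnd <- bounds[exI + 1L] - 1L
  cdsStart <- exStart[1L] + max(1L, round(0.3 * (exEnd[1L] - exStart[1L] + 1L)))
  cdsEnd <- exEnd[nEx] - max(1L, round(0.3 * (exEnd[nEx] - exStart[nEx] + 1L)))
  if (cdsStart >= cdsEnd) { cdsStart <- exStart[1L] + 1L; cdsEnd <- exEnd[nEx] - 1L }
  exons <- GRanges(chrom, IRanges(exStart, exEnd), strand = strand)
  cds <- intersect(exons, GRanges(chrom, IRanges(cdsStart, cdsEnd)),
                   ignore.strand = TRUE)
  strand(cds) <- strand
  gene <- GRanges(chrom, IRanges(gs, ge), strand = strand)
  out <- c(gene, granges(exons), granges(cds))
  mcols(out)$type <- c("gene", rep("exon", length(exons)),
                       rep("CDS", length(cds)))
  mcols(out)$gene_id <- geneId
  out
}

#' Generate a random regulatory track of a target genome fraction
#'
#' Scatters intervals with exponentially distributed lengths (mean
#' `meanLength`) uniformly over the genome, merges them, and trims so the
#' union length matches `fraction` of the genome (well within 5%).
#' Deterministic under `seed`.
#'
#' @param label track name.
#' @param fraction target genome fraction in (0, 1).
#' @param meanLength mean interval length in bp.
#' @param chromSizes named numeric vector of chromosome lengths.
#' @param seed integer seed.
#' @return A [RegulatoryTrack].
#' @export
generateTrack <- function(label, fraction, meanLength, chromSizes, seed = 1) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("infeasible track fraction: ", fraction)
  G <- sum(chromSizes)
  target <- max(1, round(fraction * G))
  withSeed(seed, {
    ## -log(1-f) corrects for overlap loss under uniform random placement
    n <- max(8L, ceiling(-G * log1p(-fraction) / meanLength))
    merged <- GRanges()
    seqlevels(merged) <- names(chromSizes)
    repeat {
      lens <- pmax(1, round(rexp(n, 1 / meanLength)))
      chrom <- sample(names(chromSizes), n, replace = TRUE,
                      prob = chromSizes)
      pos <- pmax(1, ceiling(runif(n) * chromSizes[chrom]))
      gr <- GRanges(chrom, IRanges(pos, pmin(pos + lens - 1,
                                             chromSizes[chrom])))
      merged <- reduce(c(merged, gr))
      if (sum(width(merged)) >= target) break
      n <- max(8L, ceiling((target - sum(width(merged))) / meanLength))
    }
    mergeTrack(.trimToLength(sort(merged), target), label)
  })
}

## Shrink intervals from the end of the sorted set until the union length
## equals target exactly.
.trimToLength <- function(gr, target) {
  excess <- sum(width(gr)) - target
  i <- length(gr)
  while (excess > 0 && i >= 1L) {
    d <- min(width(gr)[i], excess)
    if (d == width(gr)[i]) gr <- gr[-i] else end(gr)[i] <- end(gr)[i] - d
    excess <- excess - d
    i <- i - 1L
  }
  gr
}

## Draw point variants with random alleles until n unique keys accumulate.
## positionDraw(k) must return a width-1 GRanges of k positions.
.drawUniqueVariants <- function(n, positionDraw) {
  acc <- NULL
  k <- n
  repeat {
    gr <- positionDraw(k)
    al <- .randomAlleles(length(gr))
    df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                     ref = al$ref, alt = al$alt, stringsAsFactors = FALSE)
    acc <- if (is.null(acc)) df else rbind(acc, df)
    acc <- acc[!duplicated(makeVariantKey(acc$chrom, acc$pos, acc$ref,
                                          acc$alt)), , drop = FALSE]
    if (nrow(acc) >= n) return(acc[seq_len(n), , drop = FALSE])
    k <- n - nrow(acc)
  }
}

#' Generate a background variant pool
#'
#' Positions are uniform over the genome (unique by position and alleles);
#' allele frequencies are i.i.d. draws from `afModel`. Stands in for a full
#' SNP panel from which disease variants are later subtracted.
#'
#' @param poolSize number of variants.
#' @param chromSizes named numeric vector of chromosome lengths.
#' @param afModel AF model (see [sampleAf]).
#' @param seed integer seed.
#' @param label set label (default `"background"`).
#' @return A [VariantSet].
#' @export
generatePool <- function(poolSize, chromSizes, afModel = defaultAfModel(),
                         seed = 1, label = "background") {
  stopifnot(poolSize > 0, poolSize <= sum(chromSizes))
  genome <- genomeRanges(chromSizes)
  withSeed(seed, {
    df <- .drawUniqueVariants(poolSize,
                              function(k) .samplePositionsInRanges(genome, k))
    VariantSet(label, df$chrom, df$pos, df$ref, df$alt,
               af = sampleAf(poolSize, afModel), chromPrefix = FALSE)
  })
}

#' In-track placement probability for a planted fold-enrichment
#'
#' With track coverage `c` and fold-enrichment `lambda`, placing each
#' disease variant inside the track with probability
#' `lambda * c / (lambda * c + 1 - c)` makes the population odds ratio of
#' the disease set against a uniform background exactly `lambda`.
#'
#' @param lambda fold-enrichment (> 0).
#' @param coverage track coverage fraction in (0, 1).
#' @return Placement probability.
#' @export
#' @examples
#' plantPlacementProb(5, 0.01) # 0.04808
plantPlacementProb <- function(lambda, coverage) {
  stopifnot(lambda > 0, coverage > 0, coverage < 1)
  lambda * coverage / (lambda * coverage + 1 - coverage)
}

#' Plant a disease variant set with a known fold-enrichment
#'
#' Each variant falls inside the track with probability
#' [plantPlacementProb]`(lambda, coverage)` and lands uniformly within the
#' chosen side, so the population odds ratio versus a uniform background
#' equals `lambda` exactly. Variants may collide with pool positions; the
#' pipeline's [subtractVariants] step removes them from the background.
#'
#' @param category disease-category label.
#' @param nVariants set size.
#' @param track the [RegulatoryTrack] to enrich in.
#' @param chromSizes named numeric vector of chromosome lengths.
#' @param lambda planted fold-enrichment (> 0; 1 = no enrichment).
#' @param afModel AF model for the set (see [sampleAf]).
#' @param seed integer seed.
#' @return A [VariantSet].
#' @export
plantDiseaseSet <- function(category, nVariants, track, chromSizes,
                            lambda, afModel = defaultAfModel(), seed = 1) {
  stopifnot(is(track, "RegulatoryTrack"), nVariants > 0)
  G <- sum(chromSizes)
  coverage <- trackLength(track) / G
  p <- plantPlacementProb(lambda, coverage)
  genome <- genomeRanges(chromSizes)
  gr <- harmonizeSeqlevels(genome, trackRanges(track))
  outside <- setdiff(gr[[1L]], gr[[2L]])
  inside <- trackRanges(track)
  withSeed(seed, {
    draw <- function(k) {
      inT <- runif(k) < p
      pts <- c(.samplePositionsInRanges(inside, sum(inT)),
               .samplePositionsInRanges(outside, k - sum(inT)))
      pts
    }
    df <- .drawUniqueVariants(nVariants, draw)
    VariantSet(category, df$chrom, df$pos, df$ref, df$alt,
               af = sampleAf(nVariants, afModel), chromPrefix = FALSE)
  })
}

#' Default synthetic scenario configuration
#'
#' A toy-scale analogue of the real study design: a few-megabase genome,
#' gene models covering a realistic fraction of it, regulatory tracks at
#' coverages spanning the promoter-like (~0.1-1%) to insulator-like (~5%)
#' range, a rare-skewed background AF spectrum, and four disease categories
#' with planted fold-enrichments mirroring the strong promoter enrichment
#' of Mendelian/somatic variants, a moderate insulator-type enrichment of
#' germline cancer variants, and near-null complex variants.
#'
#' @param seed root seed recorded in (and driving) the whole scenario.
#' @return Named list accepted by [simulateScenario].
#' @export
syntheticConfig <- function(seed = 1) {
  list(
    chromSizes = c(chr1 = 2e6, chr2 = 1e6),
    nGenes = 150,
    trackSpecs = list(
      list(label = "promoter", fraction = 0.01, meanLength = 300),
      list(label = "enhancer", fraction = 0.02, meanLength = 400),
      list(label = "insulator", fraction = 0.05, meanLength = 1000)),
    poolSize = 50000,
    afModel = defaultAfModel(),
    diseaseSpecs = list(
      list(category = "mendelian", n = 2000, track = "promoter", lambda = 20),
      list(category = "cancer_somatic", n = 2000, track = "promoter", lambda = 10),
      list(category = "cancer_germline", n = 1000, track = "insulator", lambda = 10),
      list(category = "complex", n = 2000, track = "enhancer", lambda = 1.5)),
    seed = as.integer(seed))
}

#' Simulate a complete analysis scenario
#'
#' Runs every generator under seeds derived from the config's root seed:
#' genome and gene models, the genomic partition, regulatory tracks, the
#' background pool, and one planted disease set per disease spec. Disease
#' variants get their `coding` flag from overlap with the partition's
#' coding-exon class, and the background is the pool minus all disease
#' keys.
#'
#' @param config list as produced by [syntheticConfig] (fields
#'   `chromSizes`, `nGenes`, `trackSpecs`, `poolSize`, `afModel`,
#'   `diseaseSpecs`, `seed`).
#' @return Named list: `chromSizes`, `geneModels`, `partition`, `tracks`
#'   (named list), `diseaseSets` (named list), `pool`, `background`,
#'   `config`.
#' @export
simulateScenario <- function(config = syntheticConfig()) {
  .validateSyntheticConfig(config)
  nSeeds <- 2L + length(config$trackSpecs) + length(config$diseaseSpecs)
  seeds <- deriveSeeds(config$seed, nSeeds)
  geneModels <- generateGenome(config$chromSizes, config$nGenes, seeds[1L])
  partition <- buildGenomePartition(geneModels, config$chromSizes)
  tracks <- list()
  for (i in seq_along(config$trackSpecs)) {
    ts <- config$trackSpecs[[i]]
    tracks[[ts$label]] <- generateTrack(ts$label, ts$fraction, ts$meanLength,
                                        config$chromSizes, seeds[2L + i])
  }
  pool <- generatePool(config$poolSize, config$chromSizes, config$afModel,
                       seeds[2L])
  codingTrack <- partitionTrack(partition, "coding_exon")
  flagCoding <- function(vs) {
    gr <- harmonizeSeqlevels(variantRanges(vs), trackRanges(codingTrack))
    v <- variantRanges(vs)
    mcols(v)$coding <- countOverlaps(gr[[1L]], gr[[2L]],
                                     ignore.strand = TRUE) > 0L
    .variantSetFromGRanges(setLabel(vs), v)
  }
  diseaseSets <- list()
  for (i in seq_along(config$diseaseSpecs)) {
    ds <- config$diseaseSpecs[[i]]
    set <- plantDiseaseSet(ds$category, ds$n, tracks[[ds$track]],
                           config$chromSizes, ds$lambda,
                           ds$afModel %||% config$afModel,
                           seeds[2L + length(config$trackSpecs) + i])
    diseaseSets[[ds$category]] <- flagCoding(set)
  }
  pool <- flagCoding(pool)
  background <- subtractVariants(pool, diseaseSets)
  list(chromSizes = config$chromSizes, geneModels = geneModels,
       partition = partition, tracks = tracks, diseaseSets = diseaseSets,
       pool = pool, background = background, config = config)
}

.validateSyntheticConfig <- function(config) {
  need <- c("chromSizes", "nGenes", "trackSpecs", "poolSize", "afModel",
            "diseaseSpecs", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("synthetic config missing field(s): ", paste(miss, collapse = ", "))
  for (ts in config$trackSpecs)
    if (ts$fraction <= 0 || ts$fraction >= 1)
      stop("track fraction must lie in (0,1): ", ts$label)
  trackLabels <- vapply(config$trackSpecs, `[[`, "", "label")
  for (ds in config$diseaseSpecs) {
    if (ds$lambda <= 0) stop("lambda must be positive: ", ds$category)
    if (ds$n <= 0) stop("disease set size must be positive: ", ds$category)
    if (!ds$track %in% trackLabels)
      stop("disease spec '", ds$category, "' targets unknown track '",
           ds$track, "'")
  }
  invisible(TRUE)
}

#' Write a simulated scenario to standard files
#'
#' Emits the file set the pipeline consumes: `chrom.sizes`, `genes.gff3`,
#' one BED per track, one TSV per variant set (pool and disease sets), and
#' a ready-to-run pipeline config (`config.yaml`). All files are synthetic
#' data produced by the generators.
#'
#' @param scenario list from [simulateScenario].
#' @param dir output directory (created if needed).
#' @return Path to the written `config.yaml`, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(dir, "variants"), showWarnings = FALSE)
  writeChromSizes(scenario$chromSizes, file.path(dir, "chrom.sizes"))
  writeGeneModels(scenario$geneModels, file.path(dir, "genes.gff3"))
  trackPaths <- list()
  for (nm in names(scenario$tracks)) {
    p <- file.path("tracks", paste0(nm, ".bed"))
    writeBedTrack(scenario$tracks[[nm]], file.path(dir, p))
    trackPaths[[nm]] <- p
  }
  variantPaths <- list()
  for (nm in names(scenario$diseaseSets)) {
    p <- file.path("variants", paste0(nm, ".tsv"))
    writeVariantsTsv(scenario$diseaseSets[[nm]], file.path(dir, p))
    variantPaths[[nm]] <- p
  }
  writeVariantsTsv(scenario$pool, file.path(dir, "variants", "pool.tsv"))
  cfg <- list(
    chrom_sizes = "chrom.sizes",
    gene_models = "genes.gff3",
    tracks = trackPaths,
    variants = variantPaths,
    background = file.path("variants", "pool.tsv"),
    options = list(n_sets = 1000L, alpha = 0.05,
                   seed = scenario$config$seed,
                   zero_cell = "flag", flank = 2000L),
    out_dir = "results")
  path <- file.path(dir, "config.yaml")
  write_yaml(cfg, path)
  invisible(path)
}
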