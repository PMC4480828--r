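## Pipeline orchestration: config handling, stage runners, TSV reports and
## a machine-readable run manifest. The exported functions are the
## programmatic interface; inst/scripts/regvar-pipeline.R wraps them for
## shell use.

#' Read and validate a pipeline configuration
#'
#' The YAML config mirrors [writeScenario]'s output: `chrom_sizes`,
#' `gene_models`, `tracks` (label -> BED path), `variants` (category ->
#' VCF/TSV path), `background` (VCF/TSV path), an `options` section
#' (`n_sets`, `alpha`, `seed`, `zero_cell`, `flank`, optional `af_bin_edges`
#' and `noncoding_only`), and `out_dir`. Relative paths are resolved
#' against the config file's directory; referenced inputs must exist.
#'
#' @param path path to a YAML config.
#' @return Validated config list (class `regvar_config`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    p <- ifelse(grepl("^/", p), p, file.path(base, p))
    missing <- !file.exists(p)
    if (any(missing)) stop("input file not found: ", p[missing][1L])
    p
  }
  need <- setdiff(c("chrom_sizes", "tracks", "variants"), names(cfg))
  if (length(need))
    stop("config missing section(s): ", paste(need, collapse = ", "))
  cfg$chrom_sizes <- resolve(cfg$chrom_sizes)
  if (!is.null(cfg$gene_models)) cfg$gene_models <- resolve(cfg$gene_models)
  cfg$tracks <- lapply(cfg$tracks, resolve)
  cfg$variants <- lapply(cfg$variants, resolve)
  if (!is.null(cfg$background)) cfg$background <- resolve(cfg$background)
  cfg$options <- utils::modifyList(
    list(n_sets = 1000L, alpha = 0.05, seed = 1L, zero_cell = "flag",
         flank = 2000L, af_bin_edges = defaultAfBinEdges(),
         noncoding_only = FALSE),
    cfg$options %||% list())
  cfg$out_dir <- cfg$out_dir %||% "results"
  if (!grepl("^/", cfg$out_dir)) cfg$out_dir <- file.path(base, cfg$out_dir)
  class(cfg) <- c("regvar_config", "list")
  cfg
}

#' Load all inputs referenced by a pipeline config
#'
#' @param config list from [readRunConfig].
#' @return Named list: `chromSizes`, `partition` (when gene models are
#'   configured), `tracks`, `diseaseSets`, `pool`, `background` (pool minus
#'   disease keys), `options`.
#' @export
loadRunInputs <- function(config) {
  chromSizes <- readChromSizes(config$chrom_sizes)
  partition <- NULL
  if (!is.null(config$gene_models)) {
    gm <- readGeneModels(config$gene_models)
    partition <- buildGenomePartition(gm, chromSizes,
                                      flank = config$options$flank)
  }
  tracks <- lapply(names(config$tracks), function(nm)
    readBed(config$tracks[[nm]], label = nm))
  names(tracks) <- names(config$tracks)
  diseaseSets <- lapply(names(config$variants), function(nm)
    readVariants(config$variants[[nm]], category = nm))
  names(diseaseSets) <- names(config$variants)
  pool <- NULL; background <- NULL
  if (!is.null(config$background)) {
    pool <- readVariants(config$background, category = "background")
    background <- subtractVariants(pool, diseaseSets)
  }
  message("loaded ", length(tracks), " track(s), ",
          length(diseaseSets), " disease set(s)",
          if (!is.null(pool)) paste0(", pool of ", length(pool)) else "")
  list(chromSizes = chromSizes, partition = partition, tracks = tracks,
       diseaseSets = diseaseSets, pool = pool, background = background,
       options = config$options)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

## Deterministic run manifest (no timestamps, so reruns are byte-identical).
.writeManifest <- function(outDir, stage, inputs, extra = list()) {
  manifest <- c(list(
    stage = stage,
    package = "regvar",
    version = as.character(packageVersion("regvar")),
    seed = inputs$options$seed,
    n_tracks = length(inputs$tracks),
    set_sizes = lapply(inputs$diseaseSets, length),
    pool_size = if (is.null(inputs$pool)) NULL else length(inputs$pool)),
    extra)
  write_json(manifest, file.path(outDir, paste0(stage, "_manifest.json")),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

.prepOut <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config$out_dir
}

#' Run the density stage: overlap matrix and density table
#'
#' Writes `overlap_matrix.tsv` (track x genomic-class bp and percent
#' columns), `density.tsv` (per-track per-class variant counts, total
#' unique count and DVPM) and a run manifest to the config's output
#' directory. Requires gene models in the config.
#'
#' @param config list from [readRunConfig].
#' @param inputs optionally, preloaded [loadRunInputs] result.
#' @return Invisible list of output paths.
#' @export
runDensity <- function(config, inputs = loadRunInputs(config)) {
  if (is.null(inputs$partition))
    stop("the density stage needs gene_models in the config")
  outDir <- .prepOut(config)
  om <- overlapMatrix(inputs$tracks, inputs$partition)
  omDf <- data.frame(track = rownames(overlapBp(om)),
                     track_length = om@trackLength,
                     overlapBp(om), check.names = FALSE)
  pct <- overlapPct(om); colnames(pct) <- paste0(colnames(pct), "_pct")
  omDf <- cbind(omDf, pct)
  dens <- densityTable(inputs$diseaseSets, inputs$tracks, inputs$partition)
  paths <- list(overlap = file.path(outDir, "overlap_matrix.tsv"),
                density = file.path(outDir, "density.tsv"))
  .writeTsv(omDf, paths$overlap)
  .writeTsv(dens, paths$density)
  .writeManifest(outDir, "density", inputs)
  invisible(paths)
}

#' Run the background enrichment stage
#'
#' Computes the odds-ratio enrichment of every disease category in every
#' track against the genome-variant background (pool minus disease keys)
#' and writes `enrichment.tsv` with the contingency cells, OR, lnOR, SE,
#' chi-squared and p per row. With `noncoding_only` (config option or
#' argument) both disease sets and background are first restricted to
#' variants flagged noncoding.
#'
#' @param config list from [readRunConfig].
#' @param inputs optionally, preloaded [loadRunInputs] result.
#' @param noncodingOnly override the config's `noncoding_only` option.
#' @return Invisible list of output paths.
#' @export
runEnrichment <- function(config, inputs = loadRunInputs(config),
                          noncodingOnly = NULL) {
  if (is.null(inputs$background))
    stop("the enrichment stage needs a background panel in the config")
  outDir <- .prepOut(config)
  nc <- noncodingOnly %||% inputs$options$noncoding_only
  disease <- inputs$diseaseSets
  background <- inputs$background
  if (isTRUE(nc)) {
    disease <- lapply(disease, filterNoncoding)
    background <- filterNoncoding(background)
  }
  et <- enrichmentTable(disease, background, inputs$tracks,
                        zeroCell = inputs$options$zero_cell)
  path <- file.path(outDir,
                    if (isTRUE(nc)) "enrichment_noncoding.tsv"
                    else "enrichment.tsv")
  .writeTsv(et, path)
  .writeManifest(outDir, "enrichment", inputs,
                 list(noncoding_only = isTRUE(nc)))
  invisible(list(enrichment = path))
}

#' Run the matched-null stage
#'
#' For every (disease category, track) pair, resamples `n_sets`
#' allele-frequency-matched control sets from the pool and writes
#' `matched_null.tsv` (median OR, q, significant fraction, non-finite
#' count per row). With `perReplicate = TRUE` the per-replicate ORs and
#' p-values are written alongside.
#'
#' @param config list from [readRunConfig].
#' @param inputs optionally, preloaded [loadRunInputs] result.
#' @param perReplicate also write `matched_null_replicates.tsv`.
#' @return Invisible list of output paths.
#' @export
runMatchedNull <- function(config, inputs = loadRunInputs(config),
                           perReplicate = FALSE) {
  if (is.null(inputs$background))
    stop("the matched-null stage needs a background panel in the config")
  outDir <- .prepOut(config)
  opts <- inputs$options
  rows <- list(); reps <- list()
  for (d in inputs$diseaseSets) {
    for (tr in inputs$tracks) {
      res <- matchedEnrichment(d, inputs$background, tr,
                               nSets = opts$n_sets, seed = opts$seed,
                               alpha = opts$alpha,
                               edges = opts$af_bin_edges,
                               zeroCell = opts$zero_cell)
      rows[[length(rows) + 1L]] <- as.data.frame(res)
      if (perReplicate)
        reps[[length(reps) + 1L]] <- data.frame(
          category = setLabel(d), track = trackLabel(tr),
          replicate = seq_len(res@nReplicates),
          odds_ratio = replicateORs(res), p = replicatePs(res))
    }
  }
  paths <- list(matched_null = file.path(outDir, "matched_null.tsv"))
  .writeTsv(do.call(rbind, rows), paths$matched_null)
  if (perReplicate) {
    paths$replicates <- file.path(outDir, "matched_null_replicates.tsv")
    .writeTsv(do.call(rbind, reps), paths$replicates)
  }
  .writeManifest(outDir, "matched_null", inputs,
                 list(n_sets = opts$n_sets, alpha = opts$alpha))
  invisible(paths)
}

#' Run the consequence/score summary stage
#'
#' Writes `consequence_profile.tsv` (per-category per-term fractions and
#' the top-k severe fraction) and, for every numeric score column found,
#' `score_summary.tsv` rows with the configured thresholds (defaults:
#' mutation_assessor >= 1.9, gerp > 0, cadd >= 15).
#'
#' @param config list from [readRunConfig].
#' @param inputs optionally, preloaded [loadRunInputs] result.
#' @param k severity cutoff for the top-k fraction.
#' @param thresholds named list `score -> list(threshold, direction)`.
#' @return Invisible list of output paths.
#' @export
runConsequences <- function(config, inputs = loadRunInputs(config), k = 11,
                            thresholds = list(
                              mutation_assessor = list(1.9, "ge"),
                              gerp = list(0, "gt"),
                              cadd = list(15, "ge"))) {
  outDir <- .prepOut(config)
  ranking <- defaultSeverityRanking()
  profRows <- list(); scoreRows <- list()
  for (d in inputs$diseaseSets) {
    cons <- mcols(variantRanges(d))$consequence
    if (any(!is.na(cons))) {
      pr <- consequenceProfile(d, ranking, k)
      profRows[[length(profRows) + 1L]] <- data.frame(
        category = pr@categoryLabel, term = names(pr@perTermFraction),
        rank = seq_along(pr@perTermFraction),
        fraction = unname(pr@perTermFraction),
        top_k_fraction = pr@topKFraction, k = pr@k,
        n_ranked = pr@nRanked, n_unknown = pr@nUnknown)
    }
    mc <- mcols(variantRanges(d))
    for (sc in intersect(names(thresholds), colnames(mc))) {
      if (all(is.na(mc[[sc]]))) next
      th <- thresholds[[sc]]
      scoreRows[[length(scoreRows) + 1L]] <-
        scoreThresholdSummary(d, sc, th[[1L]], th[[2L]])
    }
  }
  paths <- list()
  if (length(profRows)) {
    paths$profile <- file.path(outDir, "consequence_profile.tsv")
    .writeTsv(do.call(rbind, profRows), paths$profile)
  }
  if (length(scoreRows)) {
    paths$scores <- file.path(outDir, "score_summary.tsv")
    .writeTsv(do.call(rbind, scoreRows), paths$scores)
  }
  .writeManifest(outDir, "consequences", inputs, list(k = k))
  invisible(paths)
}
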