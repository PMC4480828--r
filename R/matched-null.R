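## Matched-null layer: AF histogramming, exact-quota matched sampling,
## replicate enrichment, q summary.

#' Default allele-frequency bin edges
#'
#' Rare-end-dense edges reflecting typical disease-variant site-frequency
#' spectra; variants with missing AF form their own stratum.
#'
#' @return Numeric vector of bin edges spanning `[0, 1]`.
#' @export
defaultAfBinEdges <- function() {
  c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5, 1.0)
}

.binLabels <- function(edges) {
  n <- length(edges) - 1L
  paste0("[", edges[-length(edges)], ",", edges[-1L],
         c(rep(")", n - 1L), "]"))
}

## Bin index per AF value: bin i covers [e_i, e_{i+1}), last bin closed;
## 0 marks missing AF.
.afBinIndex <- function(af, edges) {
  idx <- integer(length(af))
  ok <- !is.na(af)
  if (any(ok)) {
    if (any(af[ok] < edges[1L] | af[ok] > edges[length(edges)]))
      stop("allele frequency outside the bin range [", edges[1L], ", ",
           edges[length(edges)], "]")
    idx[ok] <- findInterval(af[ok], edges, rightmost.closed = TRUE)
  }
  idx
}

#' Allele-frequency histogram of a variant set
#'
#' Assigns every variant to exactly one AF bin (left-closed, right-open;
#' the last bin closed) or, when its AF is missing, to a distinguished
#' missing-AF stratum, so counts always sum to the set size.
#'
#' @param vs a [VariantSet].
#' @param edges strictly increasing bin edges (default
#'   [defaultAfBinEdges]).
#' @return An [AFHistogram].
#' @export
afHistogram <- function(vs, edges = defaultAfBinEdges()) {
  stopifnot(is(vs, "VariantSet"))
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  idx <- .afBinIndex(alleleFreqs(vs), edges)
  new("AFHistogram", edges = edges,
      counts = tabulate(idx, nbins = length(edges) - 1L),
      missing = sum(idx == 0L))
}

## Per-bin index lists for a pool; element "0" holds missing-AF variants.
.poolBins <- function(pool, edges) {
  idx <- .afBinIndex(alleleFreqs(pool), edges)
  split(seq_along(idx), idx)
}

## Capacity check: pool must hold at least the target count in every bin.
.checkCapacity <- function(poolBins, target) {
  need <- c(setNames(as.list(target@counts), seq_along(target@counts)),
            list("0" = target@missing))
  for (b in names(need)) {
    k <- need[[b]]
    if (k == 0L) next
    have <- length(poolBins[[b]])
    if (have < k) {
      lab <- if (b == "0") "missing-AF stratum"
             else paste0("bin ", .binLabels(target@edges)[as.integer(b)])
      stop("insufficient pool capacity in ", lab, ": need ", k, ", have ",
           have, " (shortfall ", k - have, ")")
    }
  }
  invisible(TRUE)
}

## One matched draw: exact per-bin quotas, without replacement within the
## set. Assumes the RNG is already seeded for this replicate.
.matchedDraw <- function(poolBins, target) {
  quotas <- c(setNames(target@counts, seq_along(target@counts)),
              "0" = target@missing)
  idx <- lapply(names(quotas), function(b) {
    k <- quotas[[b]]
    if (k == 0L) return(integer())
    cand <- poolBins[[b]]
    cand[sample.int(length(cand), k)]
  })
  sort(unlist(idx, use.names = FALSE))
}

#' Sample allele-frequency-matched control sets
#'
#' Draws `nSets` control sets from the pool, each with exactly the target
#' per-bin AF counts (missing-AF variants are matched as their own
#' stratum), hence exactly the target total size. Sampling is without
#' replacement within a set and independent across sets; the whole stream
#' is reproducible from `seed`, and replicate `i` in isolation uses the
#' `i`-th derived seed.
#'
#' @param pool background [VariantSet] to draw from.
#' @param target an [AFHistogram] (typically of the disease set) or a
#'   [VariantSet] whose histogram is taken with `edges`.
#' @param nSets number of control sets.
#' @param seed integer root seed.
#' @param edges bin edges used when `target` is a [VariantSet].
#' @return List of `nSets` [VariantSet]s.
#' @export
sampleMatchedControls <- function(pool, target, nSets, seed,
                                  edges = defaultAfBinEdges()) {
  stopifnot(is(pool, "VariantSet"))
  if (is(target, "VariantSet")) target <- afHistogram(target, edges)
  stopifnot(is(target, "AFHistogram"))
  poolBins <- .poolBins(pool, target@edges)
  .checkCapacity(poolBins, target)
  seeds <- deriveSeeds(seed, nSets)
  lapply(seq_len(nSets), function(i) {
    idx <- withSeed(seeds[i], .matchedDraw(poolBins, target))
    subsetVariants(pool, idx, label = paste0(setLabel(pool), "_matched", i))
  })
}

#' Benjamini-Hochberg q summary over replicate p-values
#'
#' Applies the BH step-up adjustment to the replicate p-value list and
#' reports, as the scalar `q`, the largest adjusted value among replicates
#' whose raw p is below `alpha` (1 when none are significant). A monotone,
#' conservative summary of how consistently the replicates reject.
#'
#' @param ps replicate p-values in `[0, 1]`.
#' @param alpha raw significance threshold (default 0.05).
#' @return Single numeric q.
#' @export
#' @examples
#' qValueSummary(c(0.01, 0.02, 0.03, 0.04))
qValueSummary <- function(ps, alpha = 0.05) {
  if (!length(ps)) stop("empty p-value list")
  if (any(is.na(ps)) || any(ps < 0 | ps > 1))
    stop("p-values must lie in [0,1]")
  adj <- p.adjust(ps, method = "BH")
  sig <- ps < alpha
  if (!any(sig)) 1 else max(adj[sig])
}

#' Matched-null enrichment of a disease set in a track
#'
#' The resampling analogue of [enrichmentResult]: draws `nSets`
#' allele-frequency-matched equal-size control sets from the pool and, for
#' each replicate, builds the within/outside contingency table against the
#' disease set, recording the replicate odds ratio and Pearson chi-squared
#' p-value. Reports the exact median of the finite replicate ORs, the
#' fraction of replicates significant at `alpha`, the count of non-finite
#' replicate ORs, and the [qValueSummary] over the replicate p-values.
#'
#' @param disease disease [VariantSet].
#' @param pool background [VariantSet], key-disjoint from `disease`.
#' @param track a [RegulatoryTrack].
#' @param nSets number of matched control sets (default 1000).
#' @param seed integer root seed.
#' @param alpha per-replicate significance threshold.
#' @param edges AF bin edges.
#' @param zeroCell zero-cell policy for the replicate odds ratios (see
#'   [oddsRatio]).
#' @return A [MatchedNullResult].
#' @export
matchedEnrichment <- function(disease, pool, track, nSets = 1000, seed = 1,
                              alpha = 0.05, edges = defaultAfBinEdges(),
                              zeroCell = c("flag", "haldane")) {
  stopifnot(is(disease, "VariantSet"), is(pool, "VariantSet"),
            is(track, "RegulatoryTrack"))
  zeroCell <- match.arg(zeroCell)
  shared <- intersect(variantKeys(disease), variantKeys(pool))
  if (length(shared))
    stop("disease set and pool share ", length(shared), " variant key(s)")
  target <- afHistogram(disease, edges)
  poolBins <- .poolBins(pool, edges)
  .checkCapacity(poolBins, target)

  ## membership is fixed across replicates; precompute it once
  poolGr <- harmonizeSeqlevels(variantRanges(pool), trackRanges(track))
  inTrack <- countOverlaps(poolGr[[1L]], poolGr[[2L]],
                           ignore.strand = TRUE) > 0L
  dmw <- countVariantsInTrack(disease, track)
  nD <- length(disease)

  seeds <- deriveSeeds(seed, nSets)
  ors <- numeric(nSets); ps <- numeric(nSets)
  zeroMarginSeen <- FALSE
  for (i in seq_len(nSets)) {
    idx <- withSeed(seeds[i], .matchedDraw(poolBins, target))
    dcw <- sum(inTrack[idx])
    t <- ContingencyTable2x2(dmw, nD - dmw, dcw, length(idx) - dcw)
    ors[i] <- oddsRatio(t, zeroCell)
    chi <- withCallingHandlers(pearsonChi2(t), warning = function(w) {
      zeroMarginSeen <<- TRUE
      invokeRestart("muffleWarning")
    })
    ps[i] <- chi[["p"]]
  }
  if (zeroMarginSeen)
    warning("zero-margin contingency table(s) in replicates; affected ",
            "chi-squared statistics reported as 0 with p = 1")
  finite <- is.finite(ors)
  new("MatchedNullResult", trackLabel = trackLabel(track),
      categoryLabel = setLabel(disease), nReplicates = as.integer(nSets),
      replicateORs = ors, replicatePs = ps,
      medianOR = if (any(finite)) median(ors[finite]) else NA_real_,
      q = qValueSummary(ps, alpha), significantFraction = mean(ps < alpha),
      nNonFinite = sum(!finite), alpha = alpha, seed = as.integer(seed))
}
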