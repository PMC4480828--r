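## S4 classes. Intervals are held as unstranded GRanges in 1-based closed
## coordinates internally; BED input/output converts at the boundary.

#' RegulatoryTrack: a merged set of genomic intervals
#'
#' A named collection of genomic spans for one regulatory element type (or
#' any user-defined interval class). After construction the intervals are
#' sorted and merged: no two intervals on the same chromosome overlap or
#' abut, so [trackLength] is the union length in base pairs.
#'
#' @slot label single character, the track name.
#' @slot ranges unstranded [GenomicRanges::GRanges] holding the merged spans.
#' @export
setClass("RegulatoryTrack",
  slots = c(label = "character", ranges = "GRanges"))

setValidity("RegulatoryTrack", function(object) {
  msg <- character()
  if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
    msg <- c(msg, "label must be a single non-empty string")
  r <- object@ranges
  if (length(r)) {
    if (!all(strand(r) == "*"))
      msg <- c(msg, "ranges must be unstranded")
    red <- reduce(sort(r))
    if (length(red) != length(r) || !all(red == r))
      msg <- c(msg, "ranges must be sorted and merged (no overlap or abutment)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RegulatoryTrack (merge intervals)
#'
#' Sorts and merges a collection of intervals into a [RegulatoryTrack].
#' Overlapping and abutting intervals are unioned, so the track's total
#' length is the per-base-pair union size. Idempotent: merging a merged
#' track changes nothing.
#'
#' @param intervals a [GenomicRanges::GRanges] (strand and metadata ignored).
#' @param label track name.
#' @return A [RegulatoryTrack].
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), c(100, 150)))
#' mergeTrack(gr, "promoter")
mergeTrack <- function(intervals, label = "track") {
  stopifnot(is(intervals, "GRanges"))
  intervals <- granges(intervals)
  strand(intervals) <- "*"
  intervals <- reduce(sort(sortSeqlevels(intervals)))
  new("RegulatoryTrack", label = label, ranges = intervals)
}

#' @describeIn mergeTrack alias constructor with class-style name.
#' @export
RegulatoryTrack <- function(intervals, label = "track") mergeTrack(intervals, label)

setMethod("show", "RegulatoryTrack", function(object) {
  cat("RegulatoryTrack '", object@label, "': ", length(object@ranges),
      " intervals, ", format(trackLength(object), big.mark = ","),
      " bp\n", sep = "")
})

#' GenomePartition: the seven genomic region classes
#'
#' Holds one merged track per genomic region class derived from gene models:
#' `coding_exon`, `utr5`, `utr3`, `intron`, `upstream`, `downstream`,
#' `intergenic`. Classes are computed independently and may overlap each
#' other (e.g. an exon of one gene inside the intron of another); only
#' `intergenic` is defined by complement. Together they cover every base of
#' the genome for fully coding annotations.
#'
#' @slot classes named [GenomicRanges::GRangesList], one element per class.
#' @slot chromSizes named numeric vector of chromosome lengths (bp).
#' @export
setClass("GenomePartition",
  slots = c(classes = "GRangesList", chromSizes = "numeric"))

setValidity("GenomePartition", function(object) {
  if (is.null(names(object@classes)) || anyDuplicated(names(object@classes)))
    return("classes must be uniquely named")
  if (is.null(names(object@chromSizes)) || any(object@chromSizes <= 0))
    return("chromSizes must be named positive lengths")
  TRUE
})

setMethod("show", "GenomePartition", function(object) {
  cat("GenomePartition over", length(object@chromSizes), "chromosome(s),",
      format(sum(object@chromSizes), big.mark = ","), "bp\n")
  for (nm in names(object@classes)) {
    cat(sprintf("  %-12s %s bp\n", nm,
                format(sum(width(object@classes[[nm]])), big.mark = ",")))
  }
})

#' VariantSet: labelled point variants
#'
#' A set of point variants (position, ref and alt alleles) carrying a
#' disease-category label plus optional allele frequency, coding flag,
#' consequence term and numeric annotation scores. Variants are unique by
#' (chrom, pos, ref, alt); identical positions with different alleles are
#' distinct. Positions are 1-based; interval membership is tested on the
#' position alone, ignoring allele length.
#'
#' @slot label category name (e.g. `"mendelian"`, `"background"`).
#' @slot variants width-1 [GenomicRanges::GRanges] with metadata columns
#'   `ref`, `alt`, `id`, `af`, `coding`, `consequence` and any numeric score
#'   columns.
#' @export
setClass("VariantSet",
  slots = c(label = "character", variants = "GRanges"))

#' Canonical disease-category labels
#'
#' The four canonical disease categories plus the background label; any
#' user-defined label is also accepted wherever a category is required.
#' @export
VARIANT_CATEGORIES <- c("mendelian", "complex", "cancer_germline",
                        "cancer_somatic", "background")

.VS_CORE_COLS <- c("ref", "alt", "id", "af", "coding", "consequence")

setValidity("VariantSet", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a single non-empty string")
  v <- object@variants
  if (length(v)) {
    if (!all(width(v) == 1L))
      msg <- c(msg, "variants must be width-1 point positions")
    need <- setdiff(.VS_CORE_COLS, colnames(mcols(v)))
    if (length(need))
      msg <- c(msg, paste("missing metadata columns:", paste(need, collapse = ", ")))
    else {
      key <- makeVariantKey(as.character(seqnames(v)), start(v),
                            mcols(v)$ref, mcols(v)$alt)
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (chrom,pos,ref,alt) keys")
      af <- mcols(v)$af
      if (any(!is.na(af) & (af < 0 | af > 1)))
        msg <- c(msg, "allele frequencies must lie in [0,1]")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "VariantSet", function(object) {
  v <- object@variants
  af <- if (length(v)) mcols(v)$af else numeric()
  cat("VariantSet '", object@label, "': ", length(v), " variants (",
      sum(!is.na(af)), " with AF)\n", sep = "")
})

#' ContingencyTable2x2: within/outside counts for enrichment
#'
#' The 2x2 contingency table of the enrichment analysis: disease variants
#' within (`dmw`) and outside (`dmo`) a regulatory track, and control-group
#' variants within (`dcw`) and outside (`dco`) it.
#'
#' @slot dmw,dmo,dcw,dco non-negative counts.
#' @export
setClass("ContingencyTable2x2",
  slots = c(dmw = "numeric", dmo = "numeric", dcw = "numeric", dco = "numeric"))

setValidity("ContingencyTable2x2", function(object) {
  cells <- c(object@dmw, object@dmo, object@dcw, object@dco)
  if (length(cells) != 4L || any(is.na(cells)) || any(cells < 0))
    return("all four cells must be single non-negative counts")
  TRUE
})

#' Construct a 2x2 contingency table
#' @param dmw,dmo,dcw,dco disease/control within/outside counts.
#' @return A [ContingencyTable2x2].
#' @export
#' @examples
#' ContingencyTable2x2(10, 90, 5, 95)
ContingencyTable2x2 <- function(dmw, dmo, dcw, dco) {
  new("ContingencyTable2x2", dmw = as.numeric(dmw), dmo = as.numeric(dmo),
      dcw = as.numeric(dcw), dco = as.numeric(dco))
}

setMethod("show", "ContingencyTable2x2", function(object) {
  m <- matrix(c(object@dmw, object@dcw, object@dmo, object@dco), 2, 2,
              dimnames = list(c("disease", "control"), c("within", "outside")))
  cat("ContingencyTable2x2\n")
  print(m)
})

#' EnrichmentResult: odds-ratio enrichment for one (category, track) pair
#'
#' @slot table the underlying [ContingencyTable2x2].
#' @slot oddsRatio (dmw/dmo)/(dcw/dco); `NaN`/`Inf` flag undefined cases.
#' @slot logOR natural log of the odds ratio.
#' @slot se standard error of the log odds ratio,
#'   sqrt(1/dmw + 1/dmo + 1/dcw + 1/dco).
#' @slot chi2,p Pearson chi-squared statistic (1 df, no continuity
#'   correction) and its upper-tail probability.
#' @slot trackLabel,categoryLabel identifiers of the tested pair.
#' @export
setClass("EnrichmentResult",
  slots = c(table = "ContingencyTable2x2", oddsRatio = "numeric",
            logOR = "numeric", se = "numeric", chi2 = "numeric", p = "numeric",
            trackLabel = "character", categoryLabel = "character"))

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult %s ~ %s: OR=%.4g lnOR=%.4g SE=%.4g chi2=%.4g p=%.3g\n",
              object@categoryLabel, object@trackLabel, object@oddsRatio,
              object@logOR, object@se, object@chi2, object@p))
})

#' AFHistogram: binned allele-frequency distribution
#'
#' Counts of variants per allele-frequency bin, plus a distinguished stratum
#' for variants with missing AF so that matched sampling preserves set sizes.
#'
#' @slot edges strictly increasing bin edges spanning `[0, 1]`.
#' @slot counts integer counts per bin (length `length(edges) - 1`).
#' @slot missing count of variants with missing AF.
#' @export
setClass("AFHistogram",
  slots = c(edges = "numeric", counts = "integer", missing = "integer"))

setValidity("AFHistogram", function(object) {
  e <- object@edges
  if (length(e) < 2L || any(diff(e) <= 0))
    return("edges must be strictly increasing")
  if (length(object@counts) != length(e) - 1L)
    return("counts must have one entry per bin")
  if (any(object@counts < 0) || object@missing < 0)
    return("counts must be non-negative")
  TRUE
})

setMethod("show", "AFHistogram", function(object) {
  cat("AFHistogram:", sum(object@counts), "binned +", object@missing,
      "missing-AF\n")
  print(setNames(object@counts, .binLabels(object@edges)))
})

#' MatchedNullResult: matched-control resampling summary
#'
#' Result of testing one disease set against `nReplicates` allele-frequency
#' matched equal-size control sets: the per-replicate odds ratios and
#' chi-squared p-values, their median OR (over finite replicates), the share
#' of replicates significant at `alpha`, and a Benjamini-Hochberg q summary
#' over the replicate p-values.
#'
#' @slot trackLabel,categoryLabel tested pair.
#' @slot nReplicates number of matched control sets.
#' @slot replicateORs,replicatePs per-replicate statistics.
#' @slot medianOR exact median of the finite replicate ORs (`NA` if none).
#' @slot q maximum BH-adjusted p among replicates significant at `alpha`
#'   (1 when none are significant).
#' @slot significantFraction share of replicates with p < alpha.
#' @slot nNonFinite replicates whose OR was undefined or infinite.
#' @slot alpha per-replicate significance threshold.
#' @slot seed root seed the replicate streams were derived from.
#' @export
setClass("MatchedNullResult",
  slots = c(trackLabel = "character", categoryLabel = "character",
            nReplicates = "integer", replicateORs = "numeric",
            replicatePs = "numeric", medianOR = "numeric", q = "numeric",
            significantFraction = "numeric", nNonFinite = "integer",
            alpha = "numeric", seed = "integer"))

setValidity("MatchedNullResult", function(object) {
  if (length(object@replicateORs) != object@nReplicates ||
      length(object@replicatePs) != object@nReplicates)
    return("replicate vectors must have length nReplicates")
  TRUE
})

setMethod("show", "MatchedNullResult", function(object) {
  cat(sprintf(paste0("MatchedNullResult %s ~ %s: median OR %.4g over %d ",
                     "replicates (%d non-finite), q=%.3g, sig. fraction %.3f\n"),
              object@categoryLabel, object@trackLabel, object@medianOR,
              object@nReplicates, object@nNonFinite, object@q,
              object@significantFraction))
})

#' OverlapMatrix: regulatory tracks x genomic classes overlap
#'
#' Base-pair overlap of each regulatory track with each genomic region
#' class, and the same expressed as percent of the track length. Because the
#' classes overlap one another, row percentages may sum to more than 100.
#'
#' @slot bp numeric matrix of overlap lengths (rows = tracks, cols = classes).
#' @slot pct numeric matrix, `100 * bp / track_length` per row.
#' @slot trackLength named numeric vector of row track lengths.
#' @export
setClass("OverlapMatrix",
  slots = c(bp = "matrix", pct = "matrix", trackLength = "numeric"))

setMethod("show", "OverlapMatrix", function(object) {
  cat("OverlapMatrix:", nrow(object@bp), "track(s) x", ncol(object@bp),
      "class(es)\n")
  print(round(object@pct, 2))
})
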