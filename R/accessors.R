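## Generics and accessor methods. Slot access stays internal to the package.

#' @rdname RegulatoryTrack-class
#' @param x a [RegulatoryTrack].
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))

#' @rdname RegulatoryTrack-class
#' @export
setMethod("trackLabel", "RegulatoryTrack", function(x) x@label)

#' @rdname RegulatoryTrack-class
#' @export
setGeneric("trackRanges", function(x) standardGeneric("trackRanges"))

#' @rdname RegulatoryTrack-class
#' @export
setMethod("trackRanges", "RegulatoryTrack", function(x) x@ranges)

#' @rdname RegulatoryTrack-class
#' @export
setGeneric("trackLength", function(x) standardGeneric("trackLength"))

#' @rdname RegulatoryTrack-class
#' @export
setMethod("trackLength", "RegulatoryTrack", function(x) sum(width(x@ranges)))

setMethod("length", "RegulatoryTrack", function(x) length(x@ranges))

#' @rdname GenomePartition-class
#' @param x a [GenomePartition].
#' @export
setGeneric("partitionClasses", function(x) standardGeneric("partitionClasses"))

#' @rdname GenomePartition-class
#' @export
setMethod("partitionClasses", "GenomePartition", function(x) names(x@classes))

#' @rdname GenomePartition-class
#' @param class a class name (see [partitionClasses]).
#' @export
setGeneric("partitionTrack", function(x, class) standardGeneric("partitionTrack"))

#' @rdname GenomePartition-class
#' @export
setMethod("partitionTrack", "GenomePartition", function(x, class) {
  if (!class %in% names(x@classes))
    stop("unknown genomic class '", class, "'")
  mergeTrack(x@classes[[class]], label = class)
})

#' @rdname GenomePartition-class
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname GenomePartition-class
#' @export
setMethod("chromSizes", "GenomePartition", function(x) x@chromSizes)

#' @rdname VariantSet-class
#' @param x a [VariantSet].
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' @rdname VariantSet-class
#' @export
setMethod("setLabel", "VariantSet", function(x) x@label)

#' @rdname VariantSet-class
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname VariantSet-class
#' @export
setMethod("variantRanges", "VariantSet", function(x) x@variants)

#' @rdname VariantSet-class
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname VariantSet-class
#' @export
setMethod("variantKeys", "VariantSet", function(x) {
  v <- x@variants
  if (!length(v)) return(character())
  makeVariantKey(as.character(seqnames(v)), start(v),
                 mcols(v)$ref, mcols(v)$alt)
})

setMethod("length", "VariantSet", function(x) length(x@variants))

#' @rdname VariantSet-class
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname VariantSet-class
#' @export
setMethod("alleleFreqs", "VariantSet", function(x) mcols(x@variants)$af)

#' Coerce a VariantSet to a data.frame
#'
#' @param x a [VariantSet].
#' @param row.names,optional,... passed through (unused).
#' @return data.frame with chrom, pos, ref, alt, id, category, af, coding,
#'   consequence and any score columns.
#' @export
as.data.frame.VariantSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  v <- x@variants
  base <- data.frame(chrom = as.character(seqnames(v)), pos = start(v),
                     stringsAsFactors = FALSE)
  meta <- as.data.frame(mcols(v))
  out <- cbind(base, meta)
  out$category <- rep(x@label, nrow(out))
  out
}

#' @rdname ContingencyTable2x2-class
#' @param x a [ContingencyTable2x2].
#' @export
setGeneric("tableCells", function(x) standardGeneric("tableCells"))

#' @rdname ContingencyTable2x2-class
#' @export
setMethod("tableCells", "ContingencyTable2x2", function(x) {
  c(dmw = x@dmw, dmo = x@dmo, dcw = x@dcw, dco = x@dco)
})

#' Coerce an EnrichmentResult to a one-row data.frame
#' @param x an [EnrichmentResult].
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.EnrichmentResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  cells <- tableCells(x@table)
  data.frame(category = x@categoryLabel, track = x@trackLabel,
             dmw = cells[["dmw"]], dmo = cells[["dmo"]],
             dcw = cells[["dcw"]], dco = cells[["dco"]],
             odds_ratio = x@oddsRatio, log_or = x@logOR, se = x@se,
             chi2 = x@chi2, p = x@p, stringsAsFactors = FALSE)
}

#' @rdname MatchedNullResult-class
#' @param x a [MatchedNullResult].
#' @export
setGeneric("replicateORs", function(x) standardGeneric("replicateORs"))

#' @rdname MatchedNullResult-class
#' @export
setMethod("replicateORs", "MatchedNullResult", function(x) x@replicateORs)

#' @rdname MatchedNullResult-class
#' @export
setGeneric("replicatePs", function(x) standardGeneric("replicatePs"))

#' @rdname MatchedNullResult-class
#' @export
setMethod("replicatePs", "MatchedNullResult", function(x) x@replicatePs)

#' @rdname MatchedNullResult-class
#' @export
setGeneric("medianOR", function(x) standardGeneric("medianOR"))

#' @rdname MatchedNullResult-class
#' @export
setMethod("medianOR", "MatchedNullResult", function(x) x@medianOR)

#' @rdname MatchedNullResult-class
#' @export
setGeneric("qSummary", function(x) standardGeneric("qSummary"))

#' @rdname MatchedNullResult-class
#' @export
setMethod("qSummary", "MatchedNullResult", function(x) x@q)

#' Coerce a MatchedNullResult to a one-row data.frame
#' @param x a [MatchedNullResult].
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.MatchedNullResult <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(category = x@categoryLabel, track = x@trackLabel,
             n_replicates = x@nReplicates, median_or = x@medianOR, q = x@q,
             significant_fraction = x@significantFraction,
             n_nonfinite = x@nNonFinite, alpha = x@alpha, seed = x@seed,
             stringsAsFactors = FALSE)
}

#' @rdname OverlapMatrix-class
#' @param x an [OverlapMatrix].
#' @export
setGeneric("overlapBp", function(x) standardGeneric("overlapBp"))

#' @rdname OverlapMatrix-class
#' @export
setMethod("overlapBp", "OverlapMatrix", function(x) x@bp)

#' @rdname OverlapMatrix-class
#' @export
setGeneric("overlapPct", function(x) standardGeneric("overlapPct"))

#' @rdname OverlapMatrix-class
#' @export
setMethod("overlapPct", "OverlapMatrix", function(x) x@pct)

#' @rdname AFHistogram-class
#' @param x an [AFHistogram].
#' @export
setGeneric("histCounts", function(x) standardGeneric("histCounts"))

#' @rdname AFHistogram-class
#' @export
setMethod("histCounts", "AFHistogram", function(x) {
  c(setNames(x@counts, .binLabels(x@edges)), missing = x@missing)
})
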