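## Density layer: variant counts per track/class and DVPM.

#' Count variants falling inside a track
#'
#' Number of unique variants whose (1-based) position lies within any
#' interval of the merged track. Membership is tested on the position
#' alone.
#'
#' @param vs a [VariantSet].
#' @param track a [RegulatoryTrack].
#' @return Integer count.
#' @export
countVariantsInTrack <- function(vs, track) {
  stopifnot(is(vs, "VariantSet"), is(track, "RegulatoryTrack"))
  if (!length(vs)) return(0L)
  gr <- harmonizeSeqlevels(variantRanges(vs), trackRanges(track))
  sum(countOverlaps(gr[[1L]], gr[[2L]], ignore.strand = TRUE) > 0L)
}

#' Disease variants per million base pairs (DVPM)
#'
#' `10^6 * count / trackLength`. The float value is canonical; set
#' `rounded = TRUE` for the nearest-integer report (half rounded away from
#' zero).
#'
#' @param count unique variant count in the track.
#' @param trackLength track length in bp; must be positive.
#' @param rounded return the nearest integer instead of the float.
#' @return DVPM value.
#' @export
#' @examples
#' dvpm(4671, 19517834, rounded = TRUE) # 239
dvpm <- function(count, trackLength, rounded = FALSE) {
  if (!is.numeric(trackLength) || any(trackLength <= 0))
    stop("DVPM undefined for zero track length")
  x <- 1e6 * count / trackLength
  if (rounded) roundHalfAway(x) else x
}

## Unique union of variant positions across sets (GRanges keyed by
## chrom:pos:ref:alt).
.unionVariants <- function(variantSets) {
  if (is(variantSets, "VariantSet")) variantSets <- list(variantSets)
  grs <- lapply(variantSets, variantRanges)
  lv <- Reduce(union, lapply(grs, seqlevels))
  grs <- lapply(grs, function(g) { seqlevels(g) <- lv; g })
  all <- do.call(c, unname(grs))
  key <- makeVariantKey(as.character(seqnames(all)), start(all),
                        mcols(all)$ref, mcols(all)$alt)
  all[!duplicated(key)]
}

#' Variant counts and densities per regulatory track (density table)
#'
#' For each regulatory track: the number of unique disease variants (union
#' over the supplied sets) falling inside the track intersected with each
#' genomic region class, the total number of unique variants in the track,
#' and the DVPM. A variant lying in several (overlapping) classes is
#' counted once per class but only once in the total, so per-class counts
#' can sum to more than the total.
#'
#' @param diseaseSets list of [VariantSet]s (or a single one).
#' @param tracks list of [RegulatoryTrack]s.
#' @param partition a [GenomePartition].
#' @return data.frame with one row per track: per-class counts, total
#'   unique count, track length, DVPM (float and rounded).
#' @export
densityTable <- function(diseaseSets, tracks, partition) {
  stopifnot(is(partition, "GenomePartition"))
  if (is(tracks, "RegulatoryTrack")) tracks <- list(tracks)
  allVar <- .unionVariants(diseaseSets)
  allSet <- .variantSetFromGRanges("union", allVar)
  classes <- partitionClasses(partition)
  rows <- lapply(tracks, function(tr) {
    perClass <- vapply(classes, function(cl) {
      sub <- intersectTracks(tr, partitionTrack(partition, cl))
      countVariantsInTrack(allSet, sub)
    }, 0L)
    total <- countVariantsInTrack(allSet, tr)
    len <- trackLength(tr)
    cbind(data.frame(track = trackLabel(tr), stringsAsFactors = FALSE),
          as.data.frame(as.list(perClass)),
          data.frame(total_unique = total, track_length = len,
                     dvpm = dvpm(total, len),
                     dvpm_int = dvpm(total, len, rounded = TRUE)))
  })
  do.call(rbind, rows)
}

#' Intersect two tracks into a new track
#'
#' @param a,b [RegulatoryTrack]s.
#' @param label label of the result.
#' @return A [RegulatoryTrack] covering the per-bp intersection.
#' @export
intersectTracks <- function(a, b, label = paste(trackLabel(a), trackLabel(b),
                                                sep = "&")) {
  gr <- harmonizeSeqlevels(trackRanges(a), trackRanges(b))
  mergeTrack(intersect(gr[[1L]], gr[[2L]]), label)
}

#' Overlap matrix of regulatory tracks against genomic classes
#'
#' Computes, for every (track, class) pair, the base-pair overlap and the
#' percentage of the track covered. Tracks must be non-empty (a zero-length
#' track has no defined percentage).
#'
#' @param tracks list of [RegulatoryTrack]s.
#' @param partition a [GenomePartition].
#' @param digits decimals for the percentage matrix.
#' @return An [OverlapMatrix].
#' @export
overlapMatrix <- function(tracks, partition, digits = 2) {
  stopifnot(is(partition, "GenomePartition"))
  if (is(tracks, "RegulatoryTrack")) tracks <- list(tracks)
  lens <- vapply(tracks, trackLength, 0)
  if (any(lens == 0))
    stop("overlap percentage undefined for zero-length track '",
         trackLabel(tracks[[which(lens == 0)[1L]]]), "'")
  classes <- partitionClasses(partition)
  classTracks <- lapply(classes, partitionTrack, x = partition)
  bp <- vapply(classTracks, function(cl)
    vapply(tracks, overlapLength, 0, b = cl), numeric(length(tracks)))
  bp <- matrix(bp, nrow = length(tracks),
               dimnames = list(vapply(tracks, trackLabel, ""), classes))
  pct <- sweep(bp, 1L, lens, function(o, l) percentOverlap(o, l, digits))
  new("OverlapMatrix", bp = bp, pct = pct,
      trackLength = setNames(lens, rownames(bp)))
}
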