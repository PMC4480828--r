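## Interval layer: BED ingestion, overlap arithmetic. All coordinates are
## BED-convention 0-based half-open at the file boundary and 1-based closed
## GRanges internally.

#' Read a BED3+ file into a merged RegulatoryTrack
#'
#' Reads the first three columns (chrom, 0-based start, exclusive end) of a
#' whitespace- or tab-delimited BED file, then sorts and merges the
#' intervals (overlapping and abutting spans are unioned). `track` and
#' `browser` lines and `#` comments are ignored.
#'
#' @param path path to a BED file.
#' @param label track name; defaults to the file name without extension.
#' @param chromPrefix add a `"chr"` prefix to bare chromosome names.
#' @return A [RegulatoryTrack].
#' @seealso [writeBedTrack] for the inverse.
#' @export
readBed <- function(path, label = sub("\\.[^.]*$", "", basename(path)),
                    chromPrefix = TRUE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(mergeTrack(GRanges(), label))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("BED record with fewer than 3 columns at line ", idx[which(ncols < 3L)[1L]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start < 0
  if (any(bad))
    stop("malformed coordinate at line ", idx[which(bad)[1L]])
  rev <- end <= start
  if (any(rev))
    stop("record with end <= start rejected at line ", idx[which(rev)[1L]])
  gr <- GRanges(normalizeChrom(chrom, chromPrefix),
                IRanges(start + 1, end))
  mergeTrack(gr, label)
}

#' Write a RegulatoryTrack as BED3
#'
#' @param track a [RegulatoryTrack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedTrack <- function(track, path) {
  stopifnot(is(track, "RegulatoryTrack"))
  r <- trackRanges(track)
  df <- data.frame(chrom = as.character(seqnames(r)), start = start(r) - 1,
                   end = end(r))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path path to a `<chrom>\t<length>` text file.
#' @param chromPrefix add a `"chr"` prefix to bare chromosome names.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path, chromPrefix = TRUE) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || !is.numeric(df[[2L]]))
    stop("chrom sizes file must have <chrom> <length> columns: ", path)
  setNames(as.numeric(df[[2L]]), normalizeChrom(df[[1L]], chromPrefix))
}

#' Write a chromosome sizes file
#' @param chromSizes named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(chromSizes, path) {
  write.table(data.frame(names(chromSizes), as.integer(chromSizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total overlap between two merged tracks
#'
#' Base pairs in the intersection of two tracks; symmetric, and
#' `overlapLength(a, a)` equals `trackLength(a)`.
#'
#' @param a,b [RegulatoryTrack] objects.
#' @return Overlap size in bp.
#' @export
#' @examples
#' a <- mergeTrack(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)))
#' b <- mergeTrack(GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150)))
#' overlapLength(a, b) # 50
overlapLength <- function(a, b) {
  stopifnot(is(a, "RegulatoryTrack"), is(b, "RegulatoryTrack"))
  gr <- harmonizeSeqlevels(trackRanges(a), trackRanges(b))
  sum(width(intersect(gr[[1L]], gr[[2L]])))
}

#' Overlap as a percentage of a track's length
#'
#' @param overlapBp overlap size in bp.
#' @param trackLength track length in bp; must be positive.
#' @param digits decimals to report (2 by default; use 3 for very small
#'   percentages).
#' @return `100 * overlapBp / trackLength`, rounded to `digits`.
#' @export
#' @examples
#' percentOverlap(318864, 3833500) # 8.32
percentOverlap <- function(overlapBp, trackLength, digits = 2) {
  if (!is.numeric(trackLength) || any(trackLength <= 0))
    stop("percent overlap undefined for zero track length")
  round(100 * overlapBp / trackLength, digits)
}
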