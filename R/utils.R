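## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded package functions never perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  expr
}

## One root seed fans out into per-component / per-replicate seeds so that
## each replicate is reproducible in isolation: stream i uses the i-th value
## of sample.int() drawn immediately after set.seed(root).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Normalize chromosome names
#'
#' Adds a `"chr"` prefix where absent so tracks and variant files from mixed
#' naming conventions line up. Pass `prefix = FALSE` to leave names as-is.
#'
#' @param x character vector of chromosome names.
#' @param prefix logical; add the `"chr"` prefix when missing.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalizeChrom(c("1", "chrX"))
normalizeChrom <- function(x, prefix = TRUE) {
  x <- as.character(x)
  if (prefix) ifelse(grepl("^chr", x), x, paste0("chr", x)) else x
}

## Whole-genome GRanges (one range per chromosome) with attached Seqinfo.
genomeRanges <- function(chromSizes) {
  stopifnot(is.numeric(chromSizes), !is.null(names(chromSizes)))
  si <- Seqinfo(names(chromSizes), seqlengths = unname(chromSizes))
  GRanges(names(chromSizes), IRanges(1L, as.integer(chromSizes)), seqinfo = si)
}

## Put two GRanges on the union of their seqlevels so set operations work
## across objects built from different files.
harmonizeSeqlevels <- function(x, y) {
  lv <- union(seqlevels(x), seqlevels(y))
  seqlevels(x) <- lv
  seqlevels(y) <- lv
  list(x, y)
}

## Round half away from zero (round() rounds half to even).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

## Canonical variant key.
makeVariantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
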