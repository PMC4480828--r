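## Enrichment core: 2x2 odds ratio, log-OR standard error, Pearson
## chi-squared.

#' Build the within/outside contingency table for one (disease, control,
#' track) triple
#'
#' Disease and control sets must be key-disjoint (build the control with
#' [subtractVariants]).
#'
#' @param disease,control [VariantSet]s.
#' @param track a [RegulatoryTrack].
#' @return A [ContingencyTable2x2].
#' @export
buildContingencyTable <- function(disease, control, track) {
  shared <- intersect(variantKeys(disease), variantKeys(control))
  if (length(shared))
    stop("disease and control sets share ", length(shared),
         " variant key(s); subtract disease variants from the background first")
  dmw <- countVariantsInTrack(disease, track)
  dcw <- countVariantsInTrack(control, track)
  ContingencyTable2x2(dmw, length(disease) - dmw,
                      dcw, length(control) - dcw)
}

.cellsWithPolicy <- function(t, zeroCell = c("flag", "haldane")) {
  zeroCell <- match.arg(zeroCell)
  cells <- tableCells(t)
  if (zeroCell == "haldane" && any(cells == 0)) cells <- cells + 0.5
  cells
}

#' Odds ratio of a 2x2 table
#'
#' `(dmw/dmo) / (dcw/dco)`. With the default `zeroCell = "flag"` policy a
#' zero in `dmo`, `dcw` or `dco` yields an infinite or undefined (`NaN`)
#' value rather than silently altering the statistic;
#' `zeroCell = "haldane"` applies the Haldane-Anscombe +0.5 correction to
#' all cells when any cell is zero.
#'
#' @param t a [ContingencyTable2x2].
#' @param zeroCell `"flag"` (default) or `"haldane"`.
#' @return The odds ratio.
#' @export
#' @examples
#' oddsRatio(ContingencyTable2x2(10, 90, 5, 95)) # 2.111
oddsRatio <- function(t, zeroCell = c("flag", "haldane")) {
  cells <- .cellsWithPolicy(t, zeroCell)
  unname((cells["dmw"] / cells["dmo"]) / (cells["dcw"] / cells["dco"]))
}

#' Log odds ratio and its standard error
#'
#' Natural log of the odds ratio together with the standard error of the
#' log-OR, `sqrt(1/dmw + 1/dmo + 1/dcw + 1/dco)`. Under the default
#' zero-cell policy a zero cell yields non-finite flagged values.
#'
#' @inheritParams oddsRatio
#' @return Named numeric vector `c(log_or, se)`.
#' @export
#' @examples
#' logOrSe(ContingencyTable2x2(10, 90, 5, 95))
logOrSe <- function(t, zeroCell = c("flag", "haldane")) {
  cells <- .cellsWithPolicy(t, zeroCell)
  or <- (cells["dmw"] / cells["dmo"]) / (cells["dcw"] / cells["dco"])
  c(log_or = unname(log(or)), se = unname(sqrt(sum(1 / cells))))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' The plain Pearson statistic (no continuity correction) with expected
#' counts from the row/column margins, and the upper-tail probability on
#' 1 degree of freedom. A zero margin makes independence untestable: the
#' statistic is reported as 0 with p = 1 and a warning.
#'
#' @param t a [ContingencyTable2x2].
#' @return Named numeric vector `c(statistic, p)`.
#' @export
#' @examples
#' pearsonChi2(ContingencyTable2x2(10, 90, 5, 95))
pearsonChi2 <- function(t) {
  o <- matrix(tableCells(t)[c("dmw", "dcw", "dmo", "dco")], 2L, 2L)
  n <- sum(o)
  if (n <= 0) stop("empty contingency table")
  rs <- rowSums(o); cs <- colSums(o)
  if (any(rs == 0) || any(cs == 0)) {
    warning("zero margin in contingency table; chi-squared reported as 0")
    return(c(statistic = 0, p = 1))
  }
  e <- outer(rs, cs) / n
  stat <- sum((o - e)^2 / e)
  c(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Full enrichment result for one (disease, control, track) triple
#'
#' @inheritParams buildContingencyTable
#' @inheritParams oddsRatio
#' @return An [EnrichmentResult].
#' @export
enrichmentResult <- function(disease, control, track,
                             zeroCell = c("flag", "haldane")) {
  t <- buildContingencyTable(disease, control, track)
  or <- oddsRatio(t, zeroCell)
  ls <- logOrSe(t, zeroCell)
  chi <- pearsonChi2(t)
  new("EnrichmentResult", table = t, oddsRatio = or,
      logOR = ls[["log_or"]], se = ls[["se"]],
      chi2 = chi[["statistic"]], p = chi[["p"]],
      trackLabel = trackLabel(track), categoryLabel = setLabel(disease))
}

#' Enrichment table over categories and tracks
#'
#' Runs [enrichmentResult] for every (disease set, track) pair against one
#' control background and collects the rows (category, track, the four
#' cells, OR, lnOR, SE, chi-squared, p) into a data.frame ready for TSV
#' export or forest-style plotting of lnOR +/- SE.
#'
#' @param diseaseSets list of [VariantSet]s.
#' @param control background [VariantSet] (disease-subtracted).
#' @param tracks list of [RegulatoryTrack]s.
#' @inheritParams oddsRatio
#' @return data.frame, one row per (category, track).
#' @export
enrichmentTable <- function(diseaseSets, control, tracks,
                            zeroCell = c("flag", "haldane")) {
  if (is(diseaseSets, "VariantSet")) diseaseSets <- list(diseaseSets)
  if (is(tracks, "RegulatoryTrack")) tracks <- list(tracks)
  rows <- lapply(diseaseSets, function(d)
    lapply(tracks, function(tr)
      as.data.frame(enrichmentResult(d, control, tr, zeroCell))))
  do.call(rbind, unlist(rows, recursive = FALSE))
}
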