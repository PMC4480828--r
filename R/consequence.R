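## Consequence-severity and score-threshold summaries over externally
## supplied annotations (VEP/GWAVA/CADD/GERP/Mutation Assessor outputs are
## inputs, never computed here).

#' The shipped consequence severity ranking
#'
#' The 34 Sequence Ontology variant-consequence terms ordered from most to
#' least severe, following the Ensembl VEP ordering. Ships as an editable
#' TSV (`inst/extdata/consequence_severity.tsv`); pass your own ordered
#' character vector anywhere a ranking is accepted.
#'
#' @return Character vector of 34 terms, most severe first.
#' @export
defaultSeverityRanking <- function() {
  path <- system.file("extdata", "consequence_severity.tsv",
                      package = "regvar", mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$term[order(df$rank)]
}

#' Reduce multi-consequence annotations to the most severe term
#'
#' Splits `&`- or `,`-separated consequence strings and keeps, per variant,
#' the term with the smallest severity rank. Terms absent from the ranking
#' are kept only when no ranked term is present.
#'
#' @param terms character vector of (possibly multi-valued) consequence
#'   strings.
#' @param ranking ordered severity ranking (default
#'   [defaultSeverityRanking]).
#' @return Character vector of single terms.
#' @export
reduceToMostSevere <- function(terms, ranking = defaultSeverityRanking()) {
  vapply(strsplit(as.character(terms), "[&,]"), function(tt) {
    if (!length(tt) || all(is.na(tt))) return(NA_character_)
    tt <- trimws(tt)
    r <- match(tt, ranking)
    if (all(is.na(r))) tt[1L] else tt[which.min(r)]
  }, "")
}

#' ConsequenceProfile: severity-ranked consequence summary
#'
#' @slot categoryLabel variant category.
#' @slot perTermFraction named fractions over variants with a ranked term;
#'   sums to 1.
#' @slot topKFraction fraction of ranked variants whose severity rank is at
#'   most `k`.
#' @slot k the severity cutoff used for `topKFraction`.
#' @slot nRanked,nUnknown counts of variants with a ranked term and with a
#'   term missing from the ranking.
#' @export
setClass("ConsequenceProfile",
  slots = c(categoryLabel = "character", perTermFraction = "numeric",
            topKFraction = "numeric", k = "integer", nRanked = "integer",
            nUnknown = "integer"))

setMethod("show", "ConsequenceProfile", function(object) {
  cat(sprintf("ConsequenceProfile '%s': %d ranked variants (%d unknown), top-%d fraction %.4f\n",
              object@categoryLabel, object@nRanked, object@nUnknown,
              object@k, object@topKFraction))
})

#' Severity-ranked consequence profile of a variant set
#'
#' Tabulates the per-term fraction of annotated variants (one consequence
#' per variant; use [reduceToMostSevere] first for multi-valued
#' annotations) and the fraction whose term ranks among the `k` most
#' severe. Variants with a term not present in the ranking are counted in a
#' flagged `nUnknown` bucket and excluded from the fractions; variants with
#' no consequence are ignored.
#'
#' @param vs a [VariantSet] with `consequence` annotations.
#' @param ranking ordered severity ranking.
#' @param k severity cutoff (default 11, the most severe terms spanning
#'   transcript ablation through missense).
#' @return A [ConsequenceProfile].
#' @export
consequenceProfile <- function(vs, ranking = defaultSeverityRanking(), k = 11) {
  stopifnot(is(vs, "VariantSet"))
  cons <- mcols(variantRanges(vs))$consequence
  cons <- cons[!is.na(cons)]
  if (!length(cons)) stop("no variants carry a consequence annotation")
  ranks <- match(cons, ranking)
  known <- !is.na(ranks)
  if (!any(known))
    stop("no annotated consequence term appears in the severity ranking")
  tab <- table(factor(cons[known], levels = ranking))
  frac <- as.numeric(tab) / sum(known)
  new("ConsequenceProfile", categoryLabel = setLabel(vs),
      perTermFraction = setNames(frac, ranking),
      topKFraction = mean(ranks[known] <= k), k = as.integer(k),
      nRanked = sum(known), nUnknown = sum(!known))
}

#' Fraction of scored variants meeting a threshold
#'
#' Share of variants carrying the named score that satisfy
#' `score >= threshold` (`direction = "ge"`) or `score > threshold`
#' (`"gt"`). Unscored variants are excluded from the denominator and their
#' count reported. Typical uses: Mutation Assessor >= 1.9 for medium/high
#' functional impact, GERP > 0 for evolutionary constraint.
#'
#' @param vs a [VariantSet] with a numeric score column.
#' @param scoreName score column name (e.g. `"gerp"`,
#'   `"mutation_assessor"`).
#' @param threshold numeric threshold.
#' @param direction `"ge"` or `"gt"`.
#' @return One-row data.frame: score, threshold, direction, fraction,
#'   n_scored, n_unscored.
#' @export
scoreThresholdSummary <- function(vs, scoreName, threshold,
                                  direction = c("ge", "gt")) {
  stopifnot(is(vs, "VariantSet"))
  direction <- match.arg(direction)
  mc <- mcols(variantRanges(vs))
  if (!scoreName %in% colnames(mc))
    stop("score '", scoreName, "' absent from the variant set")
  s <- mc[[scoreName]]
  scored <- !is.na(s)
  if (!any(scored))
    stop("score '", scoreName, "' is missing for every variant")
  hit <- if (direction == "ge") s[scored] >= threshold else s[scored] > threshold
  data.frame(category = setLabel(vs), score = scoreName,
             threshold = threshold, direction = direction,
             fraction = mean(hit), n_scored = sum(scored),
             n_unscored = sum(!scored), stringsAsFactors = FALSE)
}
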