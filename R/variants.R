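## Variant data model and readers.

#' Construct a VariantSet
#'
#' Builds a labelled set of point variants unique by (chrom, pos, ref, alt).
#' Duplicate keys are collapsed (first occurrence wins) with a message
#' reporting how many were dropped.
#'
#' @param label category label (see [VARIANT_CATEGORIES]; any label is
#'   accepted).
#' @param chrom,pos,ref,alt variant coordinates (1-based position) and
#'   alleles.
#' @param id optional identifiers; synthesized from the key when absent.
#' @param af optional alternate-allele frequencies in `[0, 1]` (`NA` for
#'   missing).
#' @param coding optional logical coding flag.
#' @param consequence optional Sequence Ontology consequence terms.
#' @param scores optional data.frame of numeric annotation score columns
#'   (e.g. `gerp`, `cadd`, `mutation_assessor`).
#' @param chromPrefix add a `"chr"` prefix to bare chromosome names.
#' @return A [VariantSet].
#' @export
#' @examples
#' VariantSet("mendelian", c("chr1", "chr1"), c(100, 200), c("A", "C"),
#'            c("G", "T"), af = c(0.01, NA))
VariantSet <- function(label, chrom, pos, ref, alt, id = NULL, af = NULL,
                       coding = NULL, consequence = NULL, scores = NULL,
                       chromPrefix = TRUE) {
  n <- length(pos)
  chrom <- normalizeChrom(chrom, chromPrefix)
  pos <- as.numeric(pos)
  if (any(is.na(pos)) || any(pos < 1))
    stop("positions must be numeric and >= 1")
  fill <- function(x, default) if (is.null(x)) rep(default, n) else x
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  af <- as.numeric(fill(af, NA_real_))
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele frequencies must lie in [0,1]")
  key <- makeVariantKey(chrom, pos, ref, alt)
  id <- as.character(fill(id, NA_character_))
  id[is.na(id)] <- key[is.na(id)]
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                ref = ref, alt = alt, id = id, af = af,
                coding = fill(if (is.null(coding)) NULL else as.logical(coding), NA),
                consequence = as.character(fill(consequence, NA_character_)))
  if (!is.null(scores)) {
    scores <- as.data.frame(scores)
    stopifnot(nrow(scores) == n)
    for (nm in colnames(scores)) mcols(gr)[[nm]] <- as.numeric(scores[[nm]])
  }
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate variant record(s) collapsed in '",
            label, "'")
    gr <- gr[!dup]
  }
  gr <- sort(sortSeqlevels(gr))
  new("VariantSet", label = label, variants = gr)
}

.variantSetFromGRanges <- function(label, gr) {
  new("VariantSet", label = label, variants = sort(sortSeqlevels(gr)))
}

#' Read variants from a VCF or TSV file
#'
#' TSV files need a header with at least `chrom`, `pos`, `ref`, `alt`;
#' optional columns `id`, `af`, `coding`, `consequence` are picked up, and
#' any other numeric column is kept as an annotation score. VCF files are
#' parsed with `VariantAnnotation`; multi-allelic records are split into one
#' variant per alternate allele and the allele frequency is taken from the
#' INFO field named by `afField`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param category label assigned to the resulting set.
#' @param afField INFO field holding the alternate-allele frequency (VCF
#'   only).
#' @param chromPrefix add a `"chr"` prefix to bare chromosome names.
#' @return A [VariantSet].
#' @export
readVariants <- function(path, format = c("auto", "vcf", "tsv"),
                         category = "variants", afField = "AF",
                         chromPrefix = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
    format <- if (ext == "vcf") "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "")
    need <- setdiff(c("chrom", "pos", "ref", "alt"), colnames(df))
    if (length(need))
      stop("variant table missing mandatory column(s): ",
           paste(need, collapse = ", "))
    if (!is.numeric(df$pos))
      stop("non-numeric position in variant table: ", path)
    known <- c("chrom", "pos", "ref", "alt", "id", "af", "coding",
               "consequence", "category")
    scoreCols <- setdiff(colnames(df)[vapply(df, is.numeric, TRUE)], known)
    VariantSet(category, df$chrom, df$pos, df$ref, df$alt,
               id = df$id, af = df$af, coding = df$coding,
               consequence = df$consequence,
               scores = if (length(scoreCols)) df[scoreCols] else NULL,
               chromPrefix = chromPrefix)
  } else {
    vcf <- VariantAnnotation::readVcf(path)
    vcf <- S4Vectors::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    af <- NULL
    inf <- VariantAnnotation::info(vcf)
    if (afField %in% colnames(inf)) {
      af <- inf[[afField]]
      if (is(af, "List") || is.list(af))
        af <- vapply(af, function(x) if (length(x)) as.numeric(x[[1L]]) else NA_real_,
                     0)
      af <- as.numeric(af)
    }
    VariantSet(category,
               as.character(seqnames(rr)), start(rr),
               as.character(rr$REF), as.character(rr$ALT),
               id = names(rr), af = af, chromPrefix = chromPrefix)
  }
}

#' Write a VariantSet as a TSV file
#'
#' Emits the tabular format accepted by [readVariants] (columns `chrom`,
#' `pos`, `ref`, `alt`, `id`, `af`, `coding`, `consequence`, plus score
#' columns), so sets round-trip losslessly.
#'
#' @param vs a [VariantSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantsTsv <- function(vs, path) {
  df <- as.data.frame(vs)
  df$category <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Join allele frequencies onto a VariantSet
#'
#' Matches by the (chrom, pos, ref, alt) key. Matched variants get their
#' `af` set; unmatched variants keep a missing AF. Matched/unmatched counts
#' are reported with a message.
#'
#' @param vs a [VariantSet].
#' @param afTable either a data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `af`, or a named numeric vector keyed by `"chrom:pos:ref:alt"`.
#' @param chromPrefix normalize chromosome names in the table before
#'   matching.
#' @return A new [VariantSet] with updated `af`.
#' @export
joinAlleleFrequencies <- function(vs, afTable, chromPrefix = TRUE) {
  stopifnot(is(vs, "VariantSet"))
  if (is.data.frame(afTable)) {
    need <- setdiff(c("chrom", "pos", "ref", "alt", "af"), colnames(afTable))
    if (length(need))
      stop("afTable missing column(s): ", paste(need, collapse = ", "))
    keys <- makeVariantKey(normalizeChrom(afTable$chrom, chromPrefix),
                           afTable$pos, toupper(afTable$ref),
                           toupper(afTable$alt))
    freqs <- setNames(as.numeric(afTable$af), keys)
  } else {
    freqs <- afTable
  }
  if (any(!is.na(freqs) & (freqs < 0 | freqs > 1)))
    stop("allele frequencies must lie in [0,1]")
  gr <- variantRanges(vs)
  idx <- match(variantKeys(vs), names(freqs))
  hit <- !is.na(idx)
  mcols(gr)$af[hit] <- unname(freqs[idx[hit]])
  message(sum(hit), " variant(s) matched an allele frequency, ",
          sum(!hit), " unmatched")
  .variantSetFromGRanges(setLabel(vs), gr)
}

#' Subtract disease sets from a background panel
#'
#' Removes every variant whose key appears in any of the disease sets,
#' mirroring the construction of a genome-variant background as the full
#' SNP panel minus all disease-associated variants. Idempotent; inputs are
#' not modified.
#'
#' @param background a [VariantSet] (e.g. the full SNP panel).
#' @param diseaseSets a list of [VariantSet]s (or a single one).
#' @return A [VariantSet] with the remaining background variants.
#' @export
subtractVariants <- function(background, diseaseSets) {
  stopifnot(is(background, "VariantSet"))
  if (is(diseaseSets, "VariantSet")) diseaseSets <- list(diseaseSets)
  remove <- unique(unlist(lapply(diseaseSets, variantKeys)))
  keep <- !variantKeys(background) %in% remove
  .variantSetFromGRanges(setLabel(background),
                         variantRanges(background)[keep])
}

#' Subset a VariantSet
#'
#' @param vs a [VariantSet].
#' @param i logical or integer index over the variants.
#' @param label optional new label.
#' @return A [VariantSet].
#' @export
subsetVariants <- function(vs, i, label = setLabel(vs)) {
  .variantSetFromGRanges(label, variantRanges(vs)[i])
}

#' Keep only noncoding variants
#'
#' Filters on the per-variant `coding` flag (supplied by upstream
#' annotation or the synthetic generator); variants with a missing flag are
#' dropped.
#'
#' @param vs a [VariantSet].
#' @return A [VariantSet] with `coding == FALSE` variants.
#' @export
filterNoncoding <- function(vs) {
  cod <- mcols(variantRanges(vs))$coding
  subsetVariants(vs, !is.na(cod) & !cod)
}
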