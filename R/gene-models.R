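## Gene models and the seven-class genomic partition.

#' Read gene models from GFF3, GTF or BED12
#'
#' Imports an annotation file via `rtracklayer` and normalizes it to the
#' minimal gene-model representation used by [buildGenomePartition]: a
#' stranded `GRanges` with metadata columns `type` (one of `gene`, `exon`,
#' `CDS`) and `gene_id`. For GFF3/GTF, exon and CDS records are attached to
#' their gene through the `Parent`/`gene_id` attributes (an intermediate
#' mRNA/transcript level is resolved); for BED12, blocks become exons and
#' the thick range defines the CDS.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gff3"`, `"gtf"` or `"bed12"`.
#' @param chromPrefix add a `"chr"` prefix to bare chromosome names.
#' @return `GRanges` with `type` and `gene_id` metadata columns.
#' @export
readGeneModels <- function(path, format = c("auto", "gff3", "gtf", "bed12"),
                           chromPrefix = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", gtf = "gtf",
                     bed = "bed12", bed12 = "bed12",
                     stop("cannot infer gene-model format from '", path, "'"))
  }
  gr <- if (format == "bed12") rtracklayer::import(path, format = "bed")
        else rtracklayer::import(path, format = format)
  gm <- if (format == "bed12") .geneModelsFromBed12(gr)
        else .geneModelsFromGff(gr, gtf = format == "gtf")
  GRanges(normalizeChrom(as.character(seqnames(gm)), chromPrefix),
          ranges(gm), strand = strand(gm), type = gm$type,
          gene_id = gm$gene_id)
}

.firstParent <- function(p) {
  if (is(p, "List") || is.list(p))
    vapply(p, function(x) if (length(x)) as.character(x[[1L]]) else NA_character_, "")
  else as.character(p)
}

.geneModelsFromGff <- function(gr, gtf = FALSE) {
  type <- as.character(gr$type)
  if (gtf) {
    gid <- as.character(gr$gene_id)
  } else {
    id <- as.character(gr$ID)
    parent <- .firstParent(gr$Parent)
    geneIds <- id[type == "gene"]
    txIdx <- type %in% c("mRNA", "transcript")
    txToGene <- setNames(parent[txIdx], id[txIdx])
    resolve <- function(p) ifelse(p %in% geneIds, p,
                                  unname(txToGene[p]))
    gid <- ifelse(type == "gene", id, resolve(parent))
  }
  keep <- type %in% c("gene", "exon", "CDS")
  out <- granges(gr[keep])
  mcols(out)$type <- type[keep]
  mcols(out)$gene_id <- gid[keep]
  if (!any(out$type == "gene")) {
    ## derive gene spans from exon extents when gene rows are absent (GTF)
    ex <- out[out$type == "exon"]
    spans <- unlist(range(split(ex, ex$gene_id)))
    mcols(spans)$type <- "gene"
    mcols(spans)$gene_id <- names(spans)
    names(spans) <- NULL
    out <- c(out, spans)
  }
  if (anyNA(out$gene_id))
    stop("could not resolve gene_id for every exon/CDS record")
  out
}

.geneModelsFromBed12 <- function(gr) {
  n <- length(gr)
  gid <- if (!is.null(gr$name) && !anyNA(gr$name) && !anyDuplicated(gr$name))
    as.character(gr$name) else sprintf("gene%05d", seq_len(n))
  genes <- granges(gr)
  mcols(genes)$type <- "gene"
  mcols(genes)$gene_id <- gid
  exons <- rtracklayer::blocks(gr)
  names(exons) <- gid
  ex <- unlist(exons)
  mcols(ex)$type <- "exon"
  mcols(ex)$gene_id <- names(ex)
  names(ex) <- NULL
  cdsList <- lapply(seq_len(n), function(i) {
    th <- gr$thick[i]
    if (is.na(start(th)) || width(th) == 0L) return(GRanges())
    thickGr <- GRanges(seqnames(gr)[i], th, strand = strand(gr)[i])
    intersect(exons[[i]], granges(thickGr), ignore.strand = TRUE)
  })
  cds <- do.call(c, c(list(GRanges()), cdsList))
  if (length(cds)) {
    mcols(cds)$type <- "CDS"
    mcols(cds)$gene_id <- rep(gid, lengths(cdsList))
  }
  out <- c(genes, ex, if (length(cds)) cds else NULL)
  strand(out)[mcols(out)$type != "gene"] <-
    as.character(strand(genes))[match(mcols(out)$gene_id, gid)][mcols(out)$type != "gene"]
  out
}

#' Build the seven genomic region classes from gene models
#'
#' Derives merged tracks for `coding_exon`, `utr5`, `utr3`, `intron`,
#' `upstream`, `downstream` and `intergenic` regions. Flanks are
#' strand-aware: upstream is the `flank` bp before the transcription start
#' site and downstream the `flank` bp after the transcription end site,
#' clipped at chromosome bounds. UTRs are the exonic parts outside the CDS,
#' split by side relative to the CDS; introns are the transcript span minus
#' its exons (per gene, so overlapping genes each contribute). Intergenic is
#' the complement of gene bodies plus flanks. Classes other than intergenic
#' are computed independently and may overlap each other; no precedence is
#' applied.
#'
#' @param geneModels `GRanges` as returned by [readGeneModels] (metadata
#'   columns `type` and `gene_id`).
#' @param chromSizes named numeric vector of chromosome lengths.
#' @param flank flank size in bp (default 2000).
#' @return A [GenomePartition].
#' @export
buildGenomePartition <- function(geneModels, chromSizes, flank = 2000) {
  stopifnot(is(geneModels, "GRanges"),
            all(c("type", "gene_id") %in% colnames(mcols(geneModels))))
  si <- Seqinfo(names(chromSizes), seqlengths = unname(chromSizes))
  bad <- !as.character(seqnames(geneModels)) %in% names(chromSizes)
  if (any(bad)) {
    warning(sum(bad), " gene-model record(s) on chromosomes absent from ",
            "chromSizes dropped")
    geneModels <- geneModels[!bad]
  }
  geneModels <- GRanges(as.character(seqnames(geneModels)),
                        ranges(geneModels), strand = strand(geneModels),
                        seqinfo = si,
                        type = geneModels$type, gene_id = geneModels$gene_id)
  genes <- geneModels[geneModels$type == "gene"]
  if (!length(genes)) stop("no gene records in gene models")
  unstranded <- as.character(strand(genes)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " unstranded gene(s) treated as + strand")
    strand(genes)[unstranded] <- "+"
  }
  exons <- unstrand(geneModels[geneModels$type == "exon"])
  cds <- unstrand(geneModels[geneModels$type == "CDS"])

  exonsBy <- split(granges(exons), exons$gene_id)
  cdsBy <- split(granges(cds), cds$gene_id)

  utr5 <- GRanges(seqinfo = si); utr3 <- GRanges(seqinfo = si)
  intron <- GRanges(seqinfo = si)
  for (i in seq_along(genes)) {
    gid <- genes$gene_id[i]
    span <- unstrand(granges(genes[i]))
    ex <- if (gid %in% names(exonsBy)) exonsBy[[gid]] else span
    intron <- c(intron, setdiff(span, ex))
    if (!gid %in% names(cdsBy)) next  # noncoding gene: no UTR
    cd <- cdsBy[[gid]]
    cdsStart <- min(start(cd)); cdsEnd <- max(end(cd))
    left <- restrict(ex, end = cdsStart - 1L)
    right <- restrict(ex, start = cdsEnd + 1L)
    if (as.character(strand(genes[i])) == "+") {
      utr5 <- c(utr5, left); utr3 <- c(utr3, right)
    } else {
      utr5 <- c(utr5, right); utr3 <- c(utr3, left)
    }
  }

  ## flanks at chromosome bounds are clipped, not an error; flank() warns
  ## about the transient out-of-bound ranges that trim() then clips
  upstream <- suppressWarnings(trim(flank(granges(genes), flank, start = TRUE)))
  downstream <- suppressWarnings(trim(flank(granges(genes), flank, start = FALSE)))
  upstream <- unstrand(upstream[width(upstream) > 0L])
  downstream <- unstrand(downstream[width(downstream) > 0L])

  genome <- genomeRanges(chromSizes)
  geneFootprint <- reduce(c(unstrand(granges(genes)), upstream, downstream))
  intergenic <- setdiff(genome, geneFootprint)

  cl <- GRangesList(
    coding_exon = reduce(sort(granges(cds))),
    utr5 = reduce(sort(utr5)),
    utr3 = reduce(sort(utr3)),
    intron = reduce(sort(intron)),
    upstream = reduce(sort(upstream)),
    downstream = reduce(sort(downstream)),
    intergenic = reduce(sort(intergenic)))
  new("GenomePartition", classes = cl, chromSizes = chromSizes)
}

#' Write gene models as GFF3
#'
#' Exports the normalized gene-model `GRanges` (see [readGeneModels]) with
#' `ID` set on gene records and `Parent` on exon/CDS records, so the file
#' round-trips through [readGeneModels].
#'
#' @param geneModels `GRanges` with `type` and `gene_id` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(geneModels, path) {
  gr <- geneModels
  isGene <- gr$type == "gene"
  mcols(gr)$ID <- ifelse(isGene, gr$gene_id, NA_character_)
  mcols(gr)$Parent <- ifelse(isGene, NA_character_, gr$gene_id)
  mcols(gr)$source <- "regvar"
  mcols(gr)$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
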