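#' Read transcript models from a GTF file
#'
#' Parses exon features and groups them per transcript. GTF coordinates
#' (1-based, inclusive) are kept in the `GRanges` convention; all package
#' arithmetic that needs 0-based positions converts at the point of use.
#' Exons of each transcript are sorted by start and must not overlap;
#' introns are the gaps between consecutive exons (see
#' [transcriptIntrons()]).
#'
#' @param path GTF file with `exon` features carrying `transcript_id` and
#'   `gene_id` attributes.
#' @return A named [GenomicRanges::GRangesList], one element of exon ranges
#'   per transcript, with `gene_id` in its element metadata
#'   (`S4Vectors::mcols`). Transcript features without any exon are dropped
#'   with a warning.
#' @export
readGtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    bad <- which(body)[which(nfield < 9L)[1L]]
    stop("malformed GTF line ", bad, ": fewer than 9 tab-separated fields")
  }
  if (!any(body))
    return(GenomicRanges::GRangesList())
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  tx_feats <- gr[gr$type == "transcript"]
  missing_tx <- setdiff(tx_feats$transcript_id, ex$transcript_id)
  if (length(missing_tx))
    warning("dropping ", length(missing_tx),
            " transcript(s) with zero exons: ",
            paste(missing_tx, collapse = ", "))
  if (!length(ex)) return(GenomicRanges::GRangesList())
  exl <- S4Vectors::split(GenomicRanges::granges(ex, use.mcols = FALSE),
                          ex$transcript_id)
  exl <- S4Vectors::endoapply(exl, GenomicRanges::sort.GenomicRanges,
                              ignore.strand = TRUE)
  gene <- vapply(S4Vectors::split(ex$gene_id, ex$transcript_id),
                 function(g) g[[1L]], character(1))
  S4Vectors::mcols(exl)$gene_id <- unname(gene[names(exl)])
  exl
}

#' Write transcript models as GTF
#'
#' The inverse of [readGtf()] for the exon-level information this package
#' uses; emits one `exon` feature per exon range.
#'
#' @param transcripts a `GRangesList` as returned by [readGtf()].
#' @param path output file.
#' @param source feature source field.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(transcripts, path, source = "recsaw") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  gene <- S4Vectors::mcols(transcripts)$gene_id
  if (is.null(gene)) gene <- names(transcripts)
  for (i in seq_along(transcripts)) {
    ex <- transcripts[[i]]
    writeLines(sprintf(
      '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      as.character(GenomicRanges::seqnames(ex)), source,
      GenomicRanges::start(ex), GenomicRanges::end(ex),
      as.character(GenomicRanges::strand(ex)),
      gene[i], names(transcripts)[i]), con)
  }
  invisible(path)
}

#' Introns of each transcript
#'
#' @param transcripts a `GRangesList` of exons per transcript.
#' @return a `GRangesList` of intron ranges (gaps between consecutive exons),
#'   parallel to `transcripts`.
#' @export
transcriptIntrons <- function(transcripts) {
  rng <- unlist(range(transcripts))
  GenomicRanges::psetdiff(rng, transcripts)
}

#' Select long introns free of other genes' exons
#'
#' Keeps introns strictly longer than `minLen` base pairs that have zero
#' base-pair overlap with any exon of a transcript belonging to a different
#' gene. Overlap with other isoforms of the host gene is not disqualifying.
#'
#' @param transcripts a `GRangesList` as from [readGtf()].
#' @param minLen minimum intron length in bp (strict `>`); default 150 kb.
#' @return a `GRanges` of introns with `transcript_id` and `gene_id`
#'   metadata columns.
#' @export
selectLongIntrons <- function(transcripts, minLen = 150000L) {
  introns <- transcriptIntrons(transcripts)
  gene <- S4Vectors::mcols(transcripts)$gene_id
  if (is.null(gene)) gene <- names(transcripts)
  flat <- unlist(introns, use.names = FALSE)
  if (!length(flat)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$transcript_id <- character()
    S4Vectors::mcols(out)$gene_id <- character()
    return(out)
  }
  n_per_tx <- lengths(introns)
  flat$transcript_id <- rep(names(transcripts), n_per_tx)
  flat$gene_id <- rep(gene, n_per_tx)
  flat <- flat[GenomicRanges::width(flat) > minLen]
  if (!length(flat)) return(flat)
  all_ex <- unlist(transcripts, use.names = FALSE)
  all_ex$gene_id <- rep(gene, lengths(transcripts))
  hits <- GenomicRanges::findOverlaps(flat, all_ex, ignore.strand = TRUE)
  foreign <- flat$gene_id[S4Vectors::queryHits(hits)] !=
    all_ex$gene_id[S4Vectors::subjectHits(hits)]
  flat[!seq_along(flat) %in% S4Vectors::queryHits(hits)[foreign]]
}
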