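#' Select recursive-splicing site candidates from a junction table
#'
#' Applies the five candidate filters for recursive-splicing (RS) sites:
#' \enumerate{
#'   \item the junction lies inside a long (`> minIntron` bp) intron that is
#'     not overlapped by exons of any other gene ([selectLongIntrons()]);
#'   \item the junction is `partially_novel`: exactly one boundary matches an
#'     annotated splicing boundary, which must be the boundary of the host
#'     intron itself;
#'   \item the intronic (novel) anchor carries a splice motif: a whitelist
#'     pentamer when the novel side is a donor (known side = acceptor,
#'     [has5ssMotif()]), or a passing polypyrimidine 22-mer when the novel
#'     side is an acceptor (known side = donor, [has3ssMotif()]);
#'   \item split alignments supporting the junction have `> minOverhang` nt
#'     overhang;
#'   \item the junction spans `> minSpan` bp and the RS position is more than
#'     `minSpan` bp away from both intron boundaries.
#' }
#' All thresholds are strict inequalities. `rs_position` is reported in
#' transcription-direction bp from the intron 5' end, so downstream
#' regression is strand-agnostic. Multiple candidates in one intron are all
#' retained.
#'
#' @param junctions data.frame as from [readJunctions()]; `known_side` may be
#'   `"none"`, in which case the known side is inferred from which junction
#'   boundary coincides with the intron boundary.
#' @param transcripts `GRangesList` as from [readGtf()].
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param minIntron,minOverhang,minSpan filter thresholds (bp / nt).
#' @return data.frame with one row per candidate: `gene_id`,
#'   `transcript_id`, `chrom`, `intron_start`, `intron_end` (1-based
#'   inclusive), `strand`, `rs_position` (bp from intron 5' end),
#'   `rs_genomic` (0-based cut point), `side` (`five_prime` or
#'   `three_prime`, the motif class of the novel boundary), `known_side`,
#'   `motif`, `pyrimidine_count`, `read_count`, `max_overhang`.
#' @export
findRsCandidates <- function(junctions, transcripts, genome,
                             minIntron = 150000L, minOverhang = 10L,
                             minSpan = 5000L) {
  introns <- selectLongIntrons(transcripts, minLen = minIntron)
  out <- list()
  for (k in seq_len(nrow(junctions))) {
    j <- junctions[k, ]
    if (j$anchor_status != "partially_novel") next
    if (j$max_overhang <= minOverhang) next
    span <- j$end - j$start + 1L
    if (span <= minSpan) next
    host <- introns[as.character(GenomicRanges::seqnames(introns)) == j$chrom &
                    as.character(GenomicRanges::strand(introns)) == j$strand &
                    GenomicRanges::start(introns) <= j$start &
                    GenomicRanges::end(introns) >= j$end]
    if (!length(host)) next
    for (h in seq_along(host)) {
      intron <- host[h]
      istart <- GenomicRanges::start(intron)
      iend <- GenomicRanges::end(intron)
      ilen <- iend - istart + 1L
      minus <- j$strand == "-"
      lo_match <- j$start == istart
      hi_match <- j$end == iend
      known <- j$known_side
      if (known == "none")
        known <- if (lo_match && !hi_match) {
          if (minus) "acceptor" else "donor"
        } else if (hi_match && !lo_match) {
          if (minus) "donor" else "acceptor"
        } else "none"
      # the known boundary must be this intron's own boundary
      ok <- switch(known,
        donor = if (minus) hi_match else lo_match,
        acceptor = if (minus) lo_match else hi_match,
        FALSE)
      if (!ok) next
      # novel boundary as a 0-based genomic cut point
      novel_low <- (known == "acceptor" && !minus) ||
                   (known == "donor" && minus)
      cut <- if (novel_low) j$start - 1L else j$end
      rs_pos <- if (minus) iend - cut else cut - (istart - 1L)
      if (rs_pos <= minSpan || (ilen - rs_pos) <= minSpan) next
      # motif of the novel (intronic) anchor, transcription orientation
      if (known == "acceptor") {
        # novel donor: 5 nt downstream of the cut in transcription direction
        win <- if (minus) c(cut - 4L, cut) else c(cut + 1L, cut + 5L)
        seq5 <- .txSeq(genome, j$chrom, win[1L], win[2L], j$strand)
        if (!has5ssMotif(seq5)) next
        side <- "five_prime"; motif <- seq5; npyr <- NA_integer_
      } else {
        # novel acceptor: 22 nt upstream of the cut in transcription direction
        win <- if (minus) c(cut + 1L, cut + 22L) else c(cut - 21L, cut)
        ev <- has3ssMotif(.txSeq(genome, j$chrom, win[1L], win[2L], j$strand))
        if (!ev$passes) next
        side <- "three_prime"; motif <- ev$window_sequence
        npyr <- ev$pyrimidine_count
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = intron$gene_id, transcript_id = intron$transcript_id,
        chrom = j$chrom, intron_start = istart, intron_end = iend,
        strand = j$strand, rs_position = rs_pos, rs_genomic = cut,
        side = side, known_side = known, motif = motif,
        pyrimidine_count = npyr, read_count = j$read_count,
        max_overhang = j$max_overhang, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      rs_position = integer(), rs_genomic = integer(),
                      side = character(), known_side = character(),
                      motif = character(), pyrimidine_count = integer(),
                      read_count = integer(), max_overhang = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write an RS-candidate table
#'
#' @param candidates data.frame from [findRsCandidates()].
#' @param path output TSV; intron coordinates are written 0-based half-open.
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(candidates, path) {
  out <- candidates
  out$intron_start <- out$intron_start - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an RS-candidate table written by [writeCandidates()]
#'
#' @param path candidate TSV.
#' @return data.frame in the in-memory (1-based inclusive) convention.
#' @export
readCandidates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$intron_start <- df$intron_start + 1L
  df
}
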