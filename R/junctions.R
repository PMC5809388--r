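#' Read a splice-junction table
#'
#' Junction tables are tab-delimited with columns `chrom`, `start`, `end`
#' (0-based half-open interval of the intron spanned by the junction, donor
#' to acceptor in genomic order), `strand`, `read_count`, `max_overhang`
#' (longest split-alignment anchor, nt) and `anchor_status` (one of
#' `both_known`, `partially_novel`, `novel`). An optional eighth column
#' `known_side` (`donor`, `acceptor` or `none`) records which boundary of a
#' partially novel junction matches an annotated exon edge; when absent it
#' can be derived from the annotation with [classifyJunctionAnchors()].
#'
#' @param path TSV file, with or without a header line.
#' @return data.frame with 1-based inclusive `start`/`end` (GRanges
#'   convention) and the columns above.
#' @export
readJunctions <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- length(first) == 1L && grepl("chrom", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    cols <- c("chrom", "start", "end", "strand", "read_count",
              "max_overhang", "anchor_status", "known_side")
    names(df) <- cols[seq_len(ncol(df))]
  }
  if (!"known_side" %in% names(df)) df$known_side <- "none"
  stopifnot(all(c("chrom", "start", "end", "strand", "read_count",
                  "max_overhang", "anchor_status") %in% names(df)))
  bad <- !df$anchor_status %in% c("both_known", "partially_novel", "novel")
  if (any(bad)) stop("invalid anchor_status value(s): ",
                     paste(unique(df$anchor_status[bad]), collapse = ", "))
  if (any(df$read_count < 1L) || any(df$max_overhang < 1L))
    stop("read_count and max_overhang must be >= 1")
  # 0-based half-open on disk -> 1-based inclusive in memory
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df
}

#' Write a splice-junction table
#'
#' @param junctions data.frame in the in-memory convention of
#'   [readJunctions()].
#' @param path output TSV; coordinates are written 0-based half-open.
#' @return `path`, invisibly.
#' @export
writeJunctions <- function(junctions, path) {
  out <- junctions[c("chrom", "start", "end", "strand", "read_count",
                     "max_overhang", "anchor_status", "known_side")]
  out$start <- out$start - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Classify junction anchors against an annotation
#'
#' Reference classifier for the `anchor_status` / `known_side` columns: a
#' junction boundary is "known" when it coincides with an annotated
#' exon/intron boundary (the end of an exon for the low-coordinate side, the
#' start of an exon for the high-coordinate side). A junction with both
#' boundaries known is `both_known`, with exactly one known is
#' `partially_novel`, and with neither is `novel`. `known_side` is reported
#' in transcription orientation: the donor is the 5' side of the spanned
#' intron, which for minus-strand junctions is the high-coordinate boundary.
#'
#' @param junctions data.frame as from [readJunctions()].
#' @param transcripts a `GRangesList` as from [readGtf()].
#' @return `junctions` with recomputed `anchor_status` and `known_side`.
#' @export
classifyJunctionAnchors <- function(junctions, transcripts) {
  ex <- unlist(transcripts, use.names = FALSE)
  key <- function(chr, pos) paste(chr, pos)
  donor_lo <- key(as.character(GenomicRanges::seqnames(ex)),
                  GenomicRanges::end(ex) + 1L)     # intron start after exon
  accept_hi <- key(as.character(GenomicRanges::seqnames(ex)),
                   GenomicRanges::start(ex) - 1L)  # intron end before exon
  lo_known <- key(junctions$chrom, junctions$start) %in% donor_lo
  hi_known <- key(junctions$chrom, junctions$end) %in% accept_hi
  status <- ifelse(lo_known & hi_known, "both_known",
                   ifelse(lo_known | hi_known, "partially_novel", "novel"))
  lo_is_donor <- junctions$strand != "-"
  side <- rep("none", nrow(junctions))
  one <- xor(lo_known, hi_known)
  side[one & lo_known] <- ifelse(lo_is_donor[one & lo_known],
                                 "donor", "acceptor")
  side[one & hi_known] <- ifelse(lo_is_donor[one & hi_known],
                                 "acceptor", "donor")
  junctions$anchor_status <- status
  junctions$known_side <- side
  junctions
}
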