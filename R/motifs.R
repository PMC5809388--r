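#' Pentamers accepted as recursive 5' splice-site motifs
#'
#' The 16 pentamers found at 1% or more of annotated 5' splice sites; a
#' candidate recursive donor must start with one of these.
#'
#' @return character vector of 16 five-letter motifs.
#' @export
pentamerWhitelist <- function() {
  c("GTAAG", "GTGAG", "GTAGG", "GTATG", "GTAAA", "GTAAT", "GTGGG", "GTAAC",
    "GTCAG", "GTACG", "GTACA", "GTATT", "GTACT", "GTGTG", "GTGCG", "GTACC")
}

#' Test the 5' splice-site pentamer of a candidate recursive donor
#'
#' `seq` is the 5 nt immediately downstream of the candidate intronic 5'
#' boundary, in transcription orientation (i.e. already reverse-complemented
#' for minus-strand loci). Matching is case-insensitive; any non-ACGT
#' character (including N) fails.
#'
#' @param seq a 5-character nucleotide string.
#' @return `TRUE` if `seq` is in [pentamerWhitelist()].
#' @export
has5ssMotif <- function(seq) {
  seq <- as.character(seq)
  if (length(seq) != 1L || nchar(seq) != 5L)
    stop("5' splice-site motif must be a single 5-mer")
  toupper(seq) %in% pentamerWhitelist()
}

#' Test the 3' splice-site polypyrimidine window of a recursive acceptor
#'
#' `window` is the 22 nt at positions -22..-1 immediately upstream of the
#' candidate intronic 3' boundary, in transcription orientation. The window
#' passes if it contains more than 11 pyrimidines (C or T, counted over all
#' 22 positions) and its last three characters match YAG (Y = C or T).
#' Ambiguity characters count as non-pyrimidine.
#'
#' @param window a 22-character nucleotide string.
#' @return list with `side`, `window_sequence`, `pyrimidine_count` and
#'   `passes`.
#' @export
has3ssMotif <- function(window) {
  window <- as.character(window)
  if (length(window) != 1L || nchar(window) != 22L)
    stop("3' splice-site window must be a single 22-mer")
  up <- toupper(window)
  npyr <- sum(strsplit(up, "", fixed = TRUE)[[1L]] %in% c("C", "T"))
  list(side = "three_prime",
       window_sequence = up,
       pyrimidine_count = npyr,
       passes = npyr > 11L && grepl("[CT]AG$", up))
}

# Sequence of a genomic window in transcription orientation.
.txSeq <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome))
    stop("genome sequence lacks chromosome '", chrom, "'")
  if (start < 1L || end > Biostrings::nchar(genome[[chrom]]))
    stop("motif window [", start, ", ", end, "] outside chromosome '",
         chrom, "'")
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
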