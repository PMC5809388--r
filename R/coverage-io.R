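#' Read a bedGraph file into a CoverageTrack
#'
#' bedGraph intervals (0-based, half-open) are expanded to per-base coverage
#' over the requested `regions`; bases absent from the file get coverage 0.
#' The file must be position-sorted with non-overlapping intervals per
#' chromosome and non-negative values.
#'
#' @param path bedGraph file. Track/comment lines are ignored.
#' @param regions `GRanges` of regions to materialize.
#' @param totalMappedReads the cell's mapped-read total (positive).
#' @param cellId cell label; defaults to the file name without extension.
#' @return A [CoverageTrack-class] with raw (unnormalized) values.
#' @seealso [writeBedGraph()]
#' @export
readBedGraph <- function(path, regions, totalMappedReads,
                         cellId = sub("\\.[^.]*$", "", basename(path))) {
  n_lines <- length(readLines(path, warn = FALSE))
  gr <- if (n_lines == 0L) GenomicRanges::GRanges() else
    rtracklayer::import(path, format = "bedGraph")
  if (length(gr)) {
    if (any(gr$score < 0)) stop("bedGraph contains negative coverage values")
    by_chr <- split(gr, as.character(GenomicRanges::seqnames(gr)))
    for (chr_gr in by_chr) {
      s <- GenomicRanges::start(chr_gr)
      e <- GenomicRanges::end(chr_gr)
      if (is.unsorted(s))
        stop("bedGraph intervals are not position-sorted")
      if (length(chr_gr) > 1L && any(s[-1L] <= e[-length(e)]))
        stop("bedGraph contains overlapping intervals")
    }
  }
  g_chr <- as.character(GenomicRanges::seqnames(gr))
  g_start <- GenomicRanges::start(gr)
  g_end <- GenomicRanges::end(gr)
  vals <- lapply(seq_along(regions), function(i) {
    reg <- regions[i]
    r_start <- GenomicRanges::start(reg)
    r_end <- GenomicRanges::end(reg)
    v <- numeric(GenomicRanges::width(reg))
    if (!length(gr)) return(v)
    j <- which(g_chr == as.character(GenomicRanges::seqnames(reg)) &
                 g_start <= r_end & g_end >= r_start)
    if (!length(j)) return(v)
    lo <- pmax(g_start[j], r_start)
    hi <- pmin(g_end[j], r_end)
    len <- hi - lo + 1L
    v[sequence(len, from = lo - r_start + 1L)] <- rep(gr$score[j], len)
    v
  })
  CoverageTrack(cellId, regions, vals, totalMappedReads, normalized = FALSE)
}

#' Write a CoverageTrack as bedGraph
#'
#' Runs of equal values are merged; zero-valued runs are omitted. The output
#' is plain 4-column bedGraph with no track line, so writing is
#' byte-deterministic and a write/read round trip reproduces per-base values
#' exactly.
#'
#' @param track a [CoverageTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(track@regions)) {
    reg <- track@regions[i]
    v <- track@values[[i]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    # bedGraph is 0-based half-open
    lines <- sprintf("%s\t%d\t%d\t%s",
                     as.character(GenomicRanges::seqnames(reg)),
                     GenomicRanges::start(reg) - 1L + starts[keep] - 1L,
                     GenomicRanges::start(reg) - 1L + ends[keep],
                     formatC(r$values[keep], format = "g", digits = 15))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Depth-normalize a coverage track to counts per million
#'
#' Multiplies every per-base value by `1e6 / totalMappedReads(track)` and
#' marks the track as normalized. Normalization is guarded against being
#' applied twice.
#'
#' @param track a raw [CoverageTrack-class].
#' @return the normalized track.
#' @export
setGeneric("normalizeByDepth", function(track) standardGeneric("normalizeByDepth"))

#' @rdname normalizeByDepth
#' @export
setMethod("normalizeByDepth", "CoverageTrack", function(track) {
  if (track@normalized)
    stop("track '", track@cellId, "' is already depth-normalized")
  scale <- 1e6 / track@totalMappedReads
  track@values <- track@values * scale
  track@normalized <- TRUE
  methods::validObject(track)
  track
})

#' Sum normalized coverage tracks into a pooled track
#'
#' All tracks must be normalized and defined on identical regions. Tracks are
#' summed in `cellId` order so pooling is reproducible regardless of input
#' order; the result keeps the summed mapped-read total for bookkeeping.
#'
#' @param tracks a list of normalized [CoverageTrack-class] objects.
#' @param poolId label of the pooled track.
#' @return a pooled, normalized `CoverageTrack`.
#' @export
sumTracks <- function(tracks, poolId = "pool") {
  if (!length(tracks)) stop("need at least one track to pool")
  stopifnot(all(vapply(tracks, is, logical(1), "CoverageTrack")))
  norm <- vapply(tracks, isNormalized, logical(1))
  if (!all(norm)) stop("all tracks must be normalized before pooling")
  ref <- tracks[[1L]]
  same <- vapply(tracks, function(t)
    length(t@regions) == length(ref@regions) &&
      all(t@regions == ref@regions), logical(1))
  if (!all(same)) stop("all tracks must cover identical regions")
  tracks <- tracks[order(vapply(tracks, cellId, character(1)))]
  vals <- lapply(tracks, function(t) t@values)
  acc <- vals[[1L]]
  if (length(vals) > 1L) for (i in 2:length(vals)) acc <- acc + vals[[i]]
  CoverageTrack(poolId, ref@regions, as.list(acc),
                sum(vapply(tracks, totalMappedReads, numeric(1))),
                normalized = TRUE)
}

#' Read a directory of per-cell bedGraph files
#'
#' Loads every `*.bedGraph` file in `dir` as one [CoverageTrack-class],
#' joining each cell to its mapped-read total. File base names must match
#' the `cell_id` column of the depth table.
#'
#' @param dir directory of bedGraph files.
#' @param regions `GRanges` of regions to materialize.
#' @param depths data.frame with `cell_id` and `total_mapped_reads`, or the
#'   path of such a TSV.
#' @return named list of raw `CoverageTrack` objects, ordered by cell id.
#' @export
readCoverageDir <- function(dir, regions, depths) {
  if (is.character(depths))
    depths <- utils::read.table(depths, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  files <- sort(list.files(dir, pattern = "\\.bedGraph$", full.names = TRUE))
  if (!length(files)) stop("no .bedGraph files in ", dir)
  ids <- sub("\\.bedGraph$", "", basename(files))
  miss <- setdiff(ids, depths$cell_id)
  if (length(miss))
    stop("no mapped-read total for cell(s): ", paste(miss, collapse = ", "))
  tot <- depths$total_mapped_reads[match(ids, depths$cell_id)]
  tracks <- Map(function(f, id, tt) readBedGraph(f, regions, tt, cellId = id),
                files, ids, tot)
  names(tracks) <- ids
  tracks[order(ids)]
}
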