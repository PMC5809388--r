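#' CoverageTrack: per-base read coverage for one cell or sample
#'
#' A `CoverageTrack` holds per-base, non-negative read coverage over one or
#' more genomic regions for a single cell (or a pool of cells), together with
#' the cell's total number of mapped reads used as the depth normalizer.
#' Coverage is stored as one numeric vector per region, in genomic (left to
#' right) orientation; strand-aware extraction is done by [regionValues()].
#'
#' @slot cellId single character, the cell or pool label.
#' @slot regions a [GenomicRanges::GRanges] of disjoint regions, sorted.
#' @slot values an [IRanges::NumericList], one per-base vector per region.
#' @slot totalMappedReads single positive number, the cell's mapped-read
#'   total. Regions are a subset of the genome, so the sum of the stored
#'   coverage may legitimately exceed or fall short of this total.
#' @slot normalized logical; `TRUE` once [normalizeByDepth()] has converted
#'   raw counts to counts-per-million units.
#'
#' @seealso [CoverageTrack()], [readBedGraph()], [normalizeByDepth()],
#'   [sumTracks()]
#' @export
setClass("CoverageTrack",
  slots = c(
    cellId = "character",
    regions = "GRanges",
    values = "NumericList",
    totalMappedReads = "numeric",
    normalized = "logical"
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@cellId) != 1L || is.na(object@cellId))
    msg <- c(msg, "'cellId' must be a single non-NA string")
  if (length(object@totalMappedReads) != 1L ||
      !is.finite(object@totalMappedReads) || object@totalMappedReads <= 0)
    msg <- c(msg, "'totalMappedReads' must be a single positive number")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msg <- c(msg, "'normalized' must be TRUE or FALSE")
  if (length(object@values) != length(object@regions))
    msg <- c(msg, "'values' must have one element per region")
  else {
    w <- GenomicRanges::width(object@regions)
    len <- lengths(object@values)
    if (any(len != w))
      msg <- c(msg, "each values vector must span its region exactly")
    if (any(vapply(object@values, function(v) any(!is.finite(v)) || any(v < 0),
                   logical(1))))
      msg <- c(msg, "coverage values must be finite and non-negative")
  }
  if (length(object@regions) > 1L) {
    if (!S4Vectors::isSorted(object@regions))
      msg <- c(msg, "'regions' must be sorted")
    red <- GenomicRanges::reduce(object@regions,
                                 ignore.strand = TRUE, min.gapwidth = 0L)
    if (length(red) != length(object@regions))
      msg <- c(msg, "'regions' must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param cellId cell or pool label.
#' @param regions `GRanges` of disjoint regions (sorted by position).
#' @param values per-base coverage: a numeric vector (single region), a plain
#'   list of numeric vectors, or a `NumericList` parallel to `regions`.
#' @param totalMappedReads the cell's total mapped reads (positive).
#' @param normalized whether `values` are already in counts-per-million units.
#' @return A [CoverageTrack-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5))
#' CoverageTrack("cellA", gr, c(2, 2, 2, 0, 0), totalMappedReads = 1e6)
#' @export
CoverageTrack <- function(cellId, regions, values, totalMappedReads,
                          normalized = FALSE) {
  if (is.numeric(values)) values <- list(values)
  if (!is(values, "NumericList")) values <- IRanges::NumericList(values)
  methods::new("CoverageTrack",
    cellId = as.character(cellId), regions = regions, values = values,
    totalMappedReads = as.numeric(totalMappedReads),
    normalized = normalized)
}

#' @describeIn CoverageTrack-class the cell / pool label
#' @param object,x a `CoverageTrack`
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname CoverageTrack-class
#' @export
setMethod("cellId", "CoverageTrack", function(object) object@cellId)

#' @describeIn CoverageTrack-class the covered regions
#' @export
setGeneric("trackRegions", function(object) standardGeneric("trackRegions"))

#' @rdname CoverageTrack-class
#' @export
setMethod("trackRegions", "CoverageTrack", function(object) object@regions)

#' @describeIn CoverageTrack-class per-base values, as a `NumericList`
#' @export
setGeneric("trackValues", function(object) standardGeneric("trackValues"))

#' @rdname CoverageTrack-class
#' @export
setMethod("trackValues", "CoverageTrack", function(object) object@values)

#' @describeIn CoverageTrack-class the depth normalizer
#' @export
setGeneric("totalMappedReads",
           function(object) standardGeneric("totalMappedReads"))

#' @rdname CoverageTrack-class
#' @export
setMethod("totalMappedReads", "CoverageTrack",
          function(object) object@totalMappedReads)

#' @describeIn CoverageTrack-class has the track been depth-normalized?
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname CoverageTrack-class
#' @export
setMethod("isNormalized", "CoverageTrack", function(object) object@normalized)

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack '", object@cellId, "': ",
      length(object@regions), " region(s), ",
      sum(GenomicRanges::width(object@regions)), " bp, ",
      if (object@normalized) "normalized (per-million)" else "raw counts",
      ", total mapped reads = ", format(object@totalMappedReads),
      "\n", sep = "")
})

#' Extract per-base coverage over a sub-interval
#'
#' Pulls the per-base values of a track over `region`, which must fall inside
#' a single stored region of the track. With `orientation = "transcript"` the
#' vector is reversed for minus-strand regions so that it runs 5' to 3' in
#' transcription direction.
#'
#' @param track a [CoverageTrack-class].
#' @param region a length-1 `GRanges`.
#' @param orientation `"genomic"` (left to right) or `"transcript"`.
#' @return numeric vector of length `width(region)`.
#' @export
regionValues <- function(track, region,
                         orientation = c("genomic", "transcript")) {
  orientation <- match.arg(orientation)
  stopifnot(is(track, "CoverageTrack"), length(region) == 1L)
  hit <- which(as.character(GenomicRanges::seqnames(track@regions)) ==
                 as.character(GenomicRanges::seqnames(region)) &
               GenomicRanges::start(track@regions) <=
                 GenomicRanges::start(region) &
               GenomicRanges::end(track@regions) >= GenomicRanges::end(region))
  if (length(hit) != 1L)
    stop("region is not contained in a single track region")
  off <- GenomicRanges::start(region) - GenomicRanges::start(track@regions[hit])
  v <- track@values[[hit]][seq.int(off + 1L,
                                   off + GenomicRanges::width(region))]
  if (orientation == "transcript" &&
      as.character(GenomicRanges::strand(region)) == "-")
    v <- rev(v)
  v
}
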