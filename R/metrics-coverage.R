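#' Coverage profile by distance from the transcript 3' end
#'
#' Projects genomic coverage through each transcript's exons into transcript
#' coordinates measured from the annotated 3' end (strand-aware), then
#' reports, for each distance bin `[x_i, x_{i+1})`, the fraction `n_i / N_i`
#' where `n_i` is the number of transcripts with at least one covered base
#' in the bin and `N_i` the number of transcripts at least `x_i` nt long.
#' A base is covered when at least one read overlaps it. Callers are
#' expected to pre-filter transcripts (e.g. by expression and a minimum
#' length).
#'
#' @param transcripts `GRangesList` of exons per transcript.
#' @param track a [CoverageTrack-class] covering the transcripts.
#' @param binEdges increasing distance-bin left edges plus final right edge
#'   (bp from the 3' end); default 26 log-spaced edges from 0 to 100 kb.
#' @return data.frame with `x_lo`, `x_hi`, `n`, `N`, `fraction`.
#' @export
coverageProfile3p <- function(transcripts, track,
                              binEdges = c(0, round(10^seq(2, 5,
                                                           length.out = 25)))) {
  if (!length(transcripts)) stop("empty transcript set")
  stopifnot(!is.unsorted(binEdges, strictly = TRUE))
  covered <- lapply(seq_along(transcripts), function(i) {
    ex <- transcripts[[i]]
    v <- unlist(lapply(seq_along(ex), function(j)
      regionValues(track, ex[j])), use.names = FALSE)
    if (as.character(GenomicRanges::strand(ex))[1L] != "-") v <- rev(v)
    v > 0  # index k = distance k-1 from the 3' end
  })
  len <- vapply(covered, length, integer(1))
  nb <- length(binEdges) - 1L
  n <- N <- integer(nb)
  for (i in seq_len(nb)) {
    lo <- binEdges[i]; hi <- binEdges[i + 1L]
    N[i] <- sum(len >= lo)
    n[i] <- sum(vapply(covered, function(cv) {
      if (length(cv) <= lo) return(FALSE)
      any(cv[seq.int(lo, min(hi - 1L, length(cv) - 1L)) + 1L])
    }, logical(1)))
  }
  data.frame(x_lo = binEdges[-length(binEdges)], x_hi = binEdges[-1L],
             n = n, N = N, fraction = ifelse(N > 0, n / N, NA_real_))
}

#' Fraction of exonic bases covered by at least one read
#'
#' @param transcript `GRanges` of one transcript's exons.
#' @param track a [CoverageTrack-class].
#' @return fraction in \[0, 1\].
#' @export
exonicFractionCovered <- function(transcript, track) {
  if (!length(transcript) || sum(GenomicRanges::width(transcript)) == 0)
    stop("transcript has zero exonic length")
  v <- unlist(lapply(seq_along(transcript), function(j)
    regionValues(track, transcript[j])), use.names = FALSE)
  mean(v > 0)
}

#' Filter enhancer regions for eRNA analysis
#'
#' Drops enhancers within 2 kb (boundary gap distance, strict `< 2000`) of
#' any annotated transcript span and enhancers wider than 400 bp, then
#' attaches the 801-bp counting window (center +/- 400 bp) to each survivor.
#'
#' @param enhancers `GRanges` of enhancer intervals.
#' @param transcripts `GRangesList` of annotated transcripts (their full
#'   spans are used).
#' @param maxWidth maximum enhancer width (default 400).
#' @param minGap required distance from annotation (default 2000).
#' @return `GRanges` of retained enhancers with metadata columns `center`,
#'   `window_start`, `window_end` (1-based inclusive).
#' @export
filterEnhancers <- function(enhancers, transcripts, maxWidth = 400L,
                            minGap = 2000L) {
  keep <- GenomicRanges::width(enhancers) <= maxWidth
  if (length(transcripts)) {
    spans <- unlist(range(transcripts, ignore.strand = TRUE))
    d <- GenomicRanges::distanceToNearest(enhancers, spans,
                                          ignore.strand = TRUE)
    near <- logical(length(enhancers))
    near[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance < minGap
    keep <- keep & !near
  }
  out <- enhancers[keep]
  center <- (GenomicRanges::start(out) + GenomicRanges::end(out)) %/% 2L
  S4Vectors::mcols(out)$center <- center
  S4Vectors::mcols(out)$window_start <- center - 400L
  S4Vectors::mcols(out)$window_end <- center + 400L
  out
}

#' Call features detected from depth-normalized counts
#'
#' Normalizes raw window counts to counts per million mapped reads and calls
#' a feature detected when the normalized value strictly exceeds
#' `threshold`.
#'
#' @param counts raw counts, named by feature.
#' @param totalMapped the cell's total mapped reads (positive).
#' @param threshold detection threshold on the normalized value (default
#'   0.1, strict `>`).
#' @return data.frame with `feature_id`, `normalized_value`, `detected`,
#'   `threshold`.
#' @export
detectFeatures <- function(counts, totalMapped, threshold = 0.1) {
  if (!is.numeric(totalMapped) || length(totalMapped) != 1L ||
      totalMapped <= 0)
    stop("totalMapped must be a single positive number")
  norm <- counts * 1e6 / totalMapped
  data.frame(feature_id = if (is.null(names(counts)))
               as.character(seq_along(counts)) else names(counts),
             normalized_value = unname(norm),
             detected = unname(norm > threshold),
             threshold = threshold, stringsAsFactors = FALSE)
}

#' Per-enhancer coverage profiles around enhancer centers
#'
#' Cell-averaged normalized coverage in a symmetric window around each
#' enhancer center, as input for [aggregateEnhancerProfile()].
#'
#' @param tracks list of normalized per-cell [CoverageTrack-class] objects
#'   covering the enhancer windows.
#' @param enhancers `GRanges` from [filterEnhancers()] (metadata `center`).
#' @param flank half-window in bp (default 1000); profiles span positions
#'   `-flank .. flank - 1` relative to the center.
#' @return numeric matrix, one row per enhancer, `2 * flank` columns.
#' @export
enhancerProfileMatrix <- function(tracks, enhancers, flank = 1000L) {
  centers <- S4Vectors::mcols(enhancers)$center
  stopifnot(!is.null(centers))
  prof <- matrix(0, nrow = length(enhancers), ncol = 2L * flank)
  for (i in seq_along(enhancers)) {
    win <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(enhancers[i]),
      IRanges::IRanges(centers[i] - flank, centers[i] + flank - 1L))
    acc <- numeric(2L * flank)
    for (tr in tracks) acc <- acc + regionValues(tr, win)
    prof[i, ] <- acc / length(tracks)
  }
  rownames(prof) <- if (is.null(names(enhancers)))
    as.character(seq_along(enhancers)) else names(enhancers)
  prof
}

#' Aggregate enhancer coverage profiles
#'
#' Implements the enhancer aggregation recipe: (1) keep the enhancers in the
#' top `keepTopExpr` fraction by signal within 75-275 bp of the center (both
#' flanks summed); (2) rescale each retained profile to sum 1 (zero-signal
#' enhancers are dropped with a message); (3) sum coverage within `bin`-bp
#' bins; (4) within each bin, trim the top `trimTop` fraction of enhancers;
#' (5) average (and take the SD) across enhancers per bin.
#'
#' @param profiles matrix from [enhancerProfileMatrix()]; columns are
#'   positions `-flank .. flank - 1` relative to the enhancer center.
#' @param bin bin width in bp (default 50).
#' @param trimTop fraction of enhancers trimmed from the top per bin
#'   (default 0.01; `floor(n * trimTop)` values are removed).
#' @param keepTopExpr fraction of enhancers kept by expression (default
#'   0.70).
#' @return data.frame with `pos_lo`, `pos_hi` (bp relative to center),
#'   `mean`, `sd`, `n_enhancers`.
#' @export
aggregateEnhancerProfile <- function(profiles, bin = 50L, trimTop = 0.01,
                                     keepTopExpr = 0.70) {
  flank <- ncol(profiles) %/% 2L
  pos <- seq.int(-flank, flank - 1L)
  expr_idx <- abs(pos + 0.5) >= 75 & abs(pos + 0.5) <= 275
  score <- rowSums(profiles[, expr_idx, drop = FALSE])
  cut <- stats::quantile(score, 1 - keepTopExpr)
  profiles <- profiles[score >= cut, , drop = FALSE]
  tot <- rowSums(profiles)
  if (any(tot == 0)) {
    message("dropping ", sum(tot == 0), " zero-signal enhancer(s)")
    profiles <- profiles[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  profiles <- profiles / tot
  nb <- ncol(profiles) %/% bin
  binned <- vapply(seq_len(nb), function(i)
    rowSums(profiles[, seq.int((i - 1L) * bin + 1L, i * bin),
                     drop = FALSE]),
    numeric(nrow(profiles)))
  if (is.null(dim(binned))) binned <- matrix(binned, nrow = 1L)
  k <- floor(nrow(binned) * trimTop)
  stats_per_bin <- apply(binned, 2L, function(v) {
    if (k > 0) v <- sort(v)[seq_len(length(v) - k)]
    c(mean(v), stats::sd(v), length(v))
  })
  data.frame(pos_lo = pos[seq(1L, nb * bin, by = bin)],
             pos_hi = pos[seq(bin, nb * bin, by = bin)] + 1L,
             mean = stats_per_bin[1L, ], sd = stats_per_bin[2L, ],
             n_enhancers = stats_per_bin[3L, ])
}

#' eRNA definition from promoter histone-mark ratios
#'
#' Keeps features whose TSS-proximal `log2(H3K4me1 / H3K4me3)` ratio of
#' depth-normalized counts exceeds `cutoff` (enhancer-like chromatin). When
#' either normalized mark is zero a pseudocount is added to both and the row
#' is flagged.
#'
#' @param me1Counts,me3Counts raw read counts within the TSS window for the
#'   two marks, named by feature.
#' @param me1Total,me3Total the two libraries' mapped-read totals.
#' @param cutoff log2-ratio threshold (default 0.58, strict `>`).
#' @param pseudocount value (in normalized units) added to both marks when
#'   either is zero (default 0.5).
#' @return data.frame with `feature_id`, `log2_ratio`, `pseudo_used`,
#'   `is_eRNA`.
#' @export
histoneErnaFilter <- function(me1Counts, me3Counts, me1Total, me3Total,
                              cutoff = 0.58, pseudocount = 0.5) {
  stopifnot(length(me1Counts) == length(me3Counts),
            me1Total > 0, me3Total > 0)
  n1 <- me1Counts * 1e6 / me1Total
  n3 <- me3Counts * 1e6 / me3Total
  pseudo <- n1 == 0 | n3 == 0
  n1[pseudo] <- n1[pseudo] + pseudocount
  n3[pseudo] <- n3[pseudo] + pseudocount
  ratio <- log2(n1 / n3)
  data.frame(feature_id = if (is.null(names(me1Counts)))
               as.character(seq_along(me1Counts)) else names(me1Counts),
             log2_ratio = unname(ratio), pseudo_used = unname(pseudo),
             is_eRNA = unname(ratio > cutoff), stringsAsFactors = FALSE)
}
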