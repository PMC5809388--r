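#' Binomially thin a raw coverage track
#'
#' Each per-base count is thinned with keep probability `fraction`,
#' emulating read subsampling at the coverage level: the expectation of the
#' output is `fraction` times the input, and thinning at `a` then `b` is
#' distributionally equal to thinning once at `a * b`.
#'
#' @param track raw (integer-count) [CoverageTrack-class].
#' @param fraction keep probability in (0, 1].
#' @param seed optional integer seed; when given the draw is reproducible.
#' @return a thinned raw `CoverageTrack` (same cell id and mapped-read
#'   total; the thinning fraction is what downstream code varies).
#' @export
subsampleTrack <- function(track, fraction, seed = NULL) {
  if (isNormalized(track))
    stop("subsampling operates on raw counts, not normalized coverage")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(track)
  if (!is.null(seed)) set.seed(seed)
  vals <- lapply(as.list(track@values), function(v) {
    if (any(v != round(v))) stop("raw coverage must be integer-valued")
    out <- numeric(length(v))
    nz <- v > 0
    out[nz] <- stats::rbinom(sum(nz), as.integer(v[nz]), fraction)
    out
  })
  CoverageTrack(track@cellId, track@regions, vals, track@totalMappedReads,
                normalized = FALSE)
}

#' Estimate the number of reads mapped within an intron
#'
#' Converts summed per-base raw coverage to an approximate read count by
#' dividing by the read length.
#'
#' @param track raw [CoverageTrack-class].
#' @param intron length-1 `GRanges` (or a candidate row, see
#'   [candidateIntron()]).
#' @param readLength sequencing read length in nt (default 76).
#' @return integer read-count estimate.
#' @export
estimateIntronicReads <- function(track, intron, readLength = 76L) {
  stopifnot(readLength > 0)
  round(sum(regionValues(track, intron)) / readLength)
}

#' Intron of a candidate row as a GRanges
#'
#' @param candidate one row from [findRsCandidates()].
#' @return length-1 `GRanges`.
#' @export
candidateIntron <- function(candidate) {
  GenomicRanges::GRanges(candidate$chrom,
    IRanges::IRanges(candidate$intron_start, candidate$intron_end),
    strand = candidate$strand)
}

#' Subsampling-based sensitivity of sawtooth detection
#'
#' Repeatedly thins the pooled raw intronic coverage at each subsampling
#' fraction, reruns [detectRs()] on every thinned replicate, and records the
#' replicate's estimated intronic read count together with whether the
#' sawtooth was detected. The pooled track should come from the time point
#' of maximal host-gene expression. Fully seeded: per-replicate seeds are
#' drawn once from `seed`.
#'
#' @param track pooled raw [CoverageTrack-class].
#' @param candidate one row from [findRsCandidates()].
#' @param fractions subsampling fractions; default `10^-(0, 0.5, ..., 3)`.
#' @param reps replicates per fraction (default 100).
#' @param alpha F-test threshold passed to [detectRs()].
#' @param readLength read length for [estimateIntronicReads()].
#' @param binWidth,config passed to [detectRs()].
#' @param seed integer master seed.
#' @return data.frame with `fraction`, `replicate`, `intronic_read_count`,
#'   `detected`. Replicates with an `insufficient_data` verdict count as not
#'   detected.
#' @export
estimateSensitivity <- function(track, candidate,
                                fractions = 10^(-seq(0, 3, by = 0.5)),
                                reps = 100L, alpha = 1e-5, readLength = 76L,
                                binWidth = 5000L, config = shapeConfig(),
                                seed = 1L) {
  if (reps < 0) stop("reps must be >= 0")
  if (reps == 0L)
    return(data.frame(fraction = numeric(), replicate = integer(),
                      intronic_read_count = numeric(), detected = logical()))
  intron <- candidateIntron(candidate)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(fractions) * reps)
  grid <- expand.grid(replicate = seq_len(reps), fraction = fractions)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    f <- grid$fraction[i]
    thin <- subsampleTrack(track, f, seed = sub_seeds[i])
    cnt <- estimateIntronicReads(thin, intron, readLength)
    det <- detectRs(normalizeByDepth(thin), candidate, alpha = alpha,
                    binWidth = binWidth, config = config)
    data.frame(fraction = f, replicate = grid$replicate[i],
               intronic_read_count = cnt,
               detected = identical(det$verdict, "rs_detected"))
  })
  do.call(rbind, res)
}

#' Fit the detection-probability curve
#'
#' Logistic regression of detection on `log10(intronic_read_count + 1)`,
#' fitted by maximum likelihood. Under complete separation (every replicate
#' above some count detected, none below) the ML estimate diverges; the fit
#' then falls back to a weakly ridge-penalized logistic fit (penalty
#' `lambda * (a^2 + b^2)`, `lambda = 1e-3`) and is flagged `separable`.
#'
#' @param replicates data.frame from [estimateSensitivity()].
#' @param lambda ridge penalty used only in the separation fallback.
#' @return object of class `detectionCurve`: list with intercept `a`, slope
#'   `b`, `separable`, `covariate` (a description string) and `n`.
#' @export
fitDetectionCurve <- function(replicates, lambda = 1e-3) {
  if (nrow(replicates) < 2L || length(unique(replicates$detected)) < 2L)
    stop("need both detected and undetected replicates; ",
         "widen the subsampling fraction range")
  x <- log10(replicates$intronic_read_count + 1)
  d <- as.numeric(replicates$detected)
  separable <- max(x[d == 0]) < min(x[d == 1])
  if (!separable) {
    fit <- suppressWarnings(stats::glm(d ~ x, family = stats::binomial()))
    if (!fit$converged || any(abs(stats::coef(fit)) > 1e3))
      separable <- TRUE
    else
      ab <- unname(stats::coef(fit))
  }
  if (separable) {
    negll <- function(th)
      -sum(d * stats::plogis(th[1] + th[2] * x, log.p = TRUE) +
           (1 - d) * stats::plogis(-(th[1] + th[2] * x), log.p = TRUE)) +
        lambda * sum(th^2)
    opt <- stats::optim(c(0, 1), negll, method = "BFGS")
    ab <- opt$par
  }
  structure(list(a = ab[1L], b = ab[2L], separable = separable,
                 covariate = "log10(intronic_read_count + 1)",
                 n = nrow(replicates)),
            class = "detectionCurve")
}

#' @export
print.detectionCurve <- function(x, ...) {
  cat("Detection curve: P(detect) = logistic(",
      format(x$a, digits = 4), " + ", format(x$b, digits = 4),
      " * ", x$covariate, "), n = ", x$n,
      if (x$separable) " [separation; ridge-penalized fit]", "\n", sep = "")
  invisible(x)
}

#' Predict detection probability from a fitted curve
#'
#' @param curve a `detectionCurve` from [fitDetectionCurve()].
#' @param counts intronic read counts.
#' @return detection probabilities.
#' @export
predictDetection <- function(curve, counts) {
  stats::plogis(curve$a + curve$b * log10(counts + 1))
}

#' Serialize / restore a detection curve as JSON
#'
#' @param curve a `detectionCurve`.
#' @param path JSON file.
#' @return `path` invisibly; `readDetectionCurve` returns the curve.
#' @export
writeDetectionCurve <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDetectionCurve
#' @export
readDetectionCurve <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "detectionCurve")
}

#' Select cells with sufficient intronic reads for per-cell RS calls
#'
#' A cell is eligible when its predicted detection probability exceeds
#' `threshold` and it has at least one read-covered intronic base on both
#' sides of the RS position.
#'
#' @param cells list of raw per-cell [CoverageTrack-class] objects.
#' @param candidate one row from [findRsCandidates()].
#' @param curve a `detectionCurve` from [fitDetectionCurve()].
#' @param threshold detection-probability cut (strict `>`, default 0.95).
#' @param readLength read length for [estimateIntronicReads()].
#' @return character vector of eligible cell ids.
#' @export
selectCells <- function(cells, candidate, curve, threshold = 0.95,
                        readLength = 76L) {
  intron <- candidateIntron(candidate)
  keep <- vapply(cells, function(cell) {
    cnt <- estimateIntronicReads(cell, intron, readLength)
    if (predictDetection(curve, cnt) <= threshold) return(FALSE)
    v <- regionValues(cell, intron, orientation = "transcript")
    up <- seq_len(candidate$rs_position)
    any(v[up] > 0) && any(v[-up] > 0)
  }, logical(1))
  vapply(cells[keep], cellId, character(1))
}

#' Call recursive splicing in one cell
#'
#' Runs [detectRs()] on the cell's intronic coverage. Verdicts:
#' `rs_detected` if the sawtooth test fires; otherwise
#' `monotonic_decrease` if the baseline slope is significantly negative
#' (t-test, p < `slopeAlpha`) while the augmented model offers no
#' significant improvement; otherwise `indeterminate` (including
#' insufficient data).
#'
#' @param cell raw or normalized per-cell [CoverageTrack-class].
#' @param candidate one row from [findRsCandidates()].
#' @param alpha F-test threshold for the RS call (default 1e-5).
#' @param slopeAlpha t-test threshold for the monotonic-decrease call
#'   (default 0.05).
#' @param binWidth,config passed to [detectRs()].
#' @return list with `cell_id`, `verdict`, `p_value` (F-test),
#'   `slope_p_value` and the full `detectRs` result under `fit`.
#' @export
callRsPerCell <- function(cell, candidate, alpha = 1e-5, slopeAlpha = 0.05,
                          binWidth = 5000L, config = shapeConfig()) {
  track <- if (isNormalized(cell)) cell else normalizeByDepth(cell)
  det <- detectRs(track, candidate, alpha = alpha, binWidth = binWidth,
                  config = config)
  slope_p <- NA_real_
  verdict <- "indeterminate"
  if (det$verdict == "rs_detected") verdict <- "rs_detected"
  else if (det$verdict == "not_detected") {
    b <- det$baseline
    tstat <- b$beta1 / b$se1
    slope_p <- 2 * stats::pt(abs(tstat), b$df_resid, lower.tail = FALSE)
    if (b$beta1 < 0 && slope_p < slopeAlpha && det$p_value >= alpha)
      verdict <- "monotonic_decrease"
  }
  list(cell_id = cellId(cell), verdict = verdict, p_value = det$p_value,
       slope_p_value = slope_p, fit = det)
}
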