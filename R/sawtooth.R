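#' Bin pooled intronic coverage for sawtooth regression
#'
#' Tiles the candidate intron with `binWidth`-bp bins starting at the intron
#' 5' end in transcription direction; a terminal partial bin is dropped.
#' Each bin's value is the sum of per-base coverage within the bin, and the
#' recursive-splicing dummy `D` is 1 for bins whose midpoint lies between the
#' upstream exon and the RS position (midpoint < `rs_position`), else 0.
#'
#' @param track a (typically pooled, normalized) [CoverageTrack-class]
#'   covering the candidate intron.
#' @param candidate one row of the data.frame from [findRsCandidates()].
#' @param binWidth bin size in bp (default 5000).
#' @return list with `x` (bin midpoints, transcription-direction bp from the
#'   intron 5' end), `y` (summed coverage per bin), `D` (dummy), and `status`
#'   (`"ok"` or `"insufficient_data"` when fewer than 6 bins are available
#'   or the intron carries no coverage at all).
#' @export
binCoverage <- function(track, candidate, binWidth = 5000L) {
  intron <- GenomicRanges::GRanges(candidate$chrom,
    IRanges::IRanges(candidate$intron_start, candidate$intron_end),
    strand = candidate$strand)
  v <- regionValues(track, intron, orientation = "transcript")
  nb <- length(v) %/% binWidth
  if (nb < 6L)
    return(list(x = numeric(), y = numeric(), D = numeric(),
                status = "insufficient_data"))
  y <- colSums(matrix(v[seq_len(nb * binWidth)], nrow = binWidth))
  x <- (seq_len(nb) - 0.5) * binWidth
  D <- as.numeric(x < candidate$rs_position)
  status <- if (all(y == 0)) "insufficient_data" else "ok"
  list(x = x, y = y, D = D, status = status)
}

#' Ordinary least-squares fit of the baseline or augmented sawtooth model
#'
#' Baseline model: `y ~ 1 + x` (coverage against genomic position in
#' transcription direction). Augmented model: `y ~ 1 + x + D`, where `D`
#' marks bins upstream of the RS site. Plain OLS via [stats::lm()].
#'
#' @param x bin positions.
#' @param y bin coverage values.
#' @param D optional dummy; omit (`NULL`) for the baseline model.
#' @return list with `beta0`, `beta1`, `beta2` (`NA` for baseline), their
#'   standard errors `se0`/`se1`/`se2`, `rss`, `df_resid` and `n`.
#' @export
fitLinear <- function(x, y, D = NULL) {
  n <- length(y)
  p <- if (is.null(D)) 2L else 3L
  if (n < p + 1L) stop("too few observations for ", p, "-parameter fit")
  if (length(unique(x)) < 2L) stop("x is constant; design is rank-deficient")
  fit <- if (is.null(D)) stats::lm(y ~ x) else stats::lm(y ~ x + D)
  if (fit$rank < p)
    stop("rank-deficient design (is the dummy constant?)")
  cf <- stats::coef(fit)
  # vcov warns on numerically perfect fits; those are legitimate here
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  list(beta0 = unname(cf[1L]), beta1 = unname(cf[2L]),
       beta2 = if (p == 3L) unname(cf[3L]) else NA_real_,
       se0 = unname(se[1L]), se1 = unname(se[2L]),
       se2 = if (p == 3L) unname(se[3L]) else NA_real_,
       rss = sum(stats::residuals(fit)^2),
       df_resid = stats::df.residual(fit), n = n)
}

#' F-test comparing the baseline and augmented sawtooth fits
#'
#' `F = ((rss_base - rss_aug) / 1) / (rss_aug / df_aug)` with a p-value from
#' the F distribution on `(1, df_aug)` degrees of freedom. A perfect
#' augmented fit (`rss_aug = 0` with `rss_base > 0`) yields `p = 0` by
#' convention; identical fits yield `F = 0`, `p = 1`.
#'
#' @param baseline,augmented fits from [fitLinear()] on the same response;
#'   the augmented model must nest the baseline with one extra parameter.
#' @return list with `f_stat` and `p_value`.
#' @export
fTest <- function(baseline, augmented) {
  if (augmented$df_resid != baseline$df_resid - 1L)
    stop("augmented model must add exactly one parameter")
  tol <- 1e-9 * max(1, baseline$rss)
  if (augmented$rss > baseline$rss + tol)
    stop("augmented RSS exceeds baseline RSS; models are not nested")
  num <- max(baseline$rss - augmented$rss, 0)
  if (augmented$rss <= tol) {
    if (num <= tol) return(list(f_stat = 0, p_value = 1))
    return(list(f_stat = Inf, p_value = 0))
  }
  f <- num / (augmented$rss / augmented$df_resid)
  list(f_stat = f,
       p_value = stats::pf(f, 1, augmented$df_resid, lower.tail = FALSE))
}

#' Shape-criterion configuration for sawtooth calls
#'
#' The four shape criteria applied to the fitted models, all configurable:
#' the augmented slope must be negative (nascent coverage decays 5' to 3'),
#' the coverage reset at the RS site must be positive, the augmented
#' intercept must be positive, and the augmented/baseline slope ratio must
#' fall within `[ratioLo, ratioHi]`.
#'
#' With the dummy coded 1 upstream of the RS site, an upward sawtooth reset
#' corresponds to a negative dummy coefficient; the reset height reported and
#' thresholded here is `-beta2`.
#'
#' @param slopeMax upper bound for the augmented slope (default 0).
#' @param stepMin lower bound for the RS reset height `-beta2` (default 0).
#' @param interceptMin lower bound for the augmented intercept (default 0).
#' @param ratioLo,ratioHi admissible range of `beta1_aug / beta1_base`
#'   (defaults 0.2 and 5).
#' @return named list of thresholds.
#' @export
shapeConfig <- function(slopeMax = 0, stepMin = 0, interceptMin = 0,
                        ratioLo = 0.2, ratioHi = 5) {
  list(slopeMax = slopeMax, stepMin = stepMin, interceptMin = interceptMin,
       ratioLo = ratioLo, ratioHi = ratioHi)
}

#' Apply the sawtooth shape criteria
#'
#' @param baseline,augmented fits from [fitLinear()].
#' @param config thresholds from [shapeConfig()].
#' @return named logical vector with flags `slope_negative`,
#'   `rs_step_positive`, `intercept_positive`, `slope_ratio_in_range`. A zero
#'   baseline slope makes the ratio flag `FALSE`.
#' @export
shapeCheck <- function(baseline, augmented, config = shapeConfig()) {
  ratio_ok <- if (baseline$beta1 == 0) FALSE else {
    r <- augmented$beta1 / baseline$beta1
    r >= config$ratioLo && r <= config$ratioHi
  }
  c(slope_negative = augmented$beta1 < config$slopeMax,
    rs_step_positive = -augmented$beta2 > config$stepMin,
    intercept_positive = augmented$beta0 > config$interceptMin,
    slope_ratio_in_range = ratio_ok)
}

#' Detect a sawtooth (recursive-splicing) signature at one candidate
#'
#' Composes [binCoverage()], the two [fitLinear()] fits, [fTest()] and
#' [shapeCheck()]. The verdict is `rs_detected` when the F-test p-value is
#' below `alpha` and all four shape flags hold; `insufficient_data` when
#' fewer than 6 full bins or no coverage are available; otherwise
#' `not_detected`.
#'
#' @param track pooled normalized [CoverageTrack-class].
#' @param candidate one row from [findRsCandidates()].
#' @param alpha F-test significance threshold (default 1e-5).
#' @param binWidth bin size in bp.
#' @param config shape thresholds from [shapeConfig()].
#' @return list with `candidate` (gene/transcript/rs ids), `baseline`,
#'   `augmented`, `f_stat`, `p_value`, `shape_flags`, `verdict`, plus the
#'   binning under `bins`.
#' @export
detectRs <- function(track, candidate, alpha = 1e-5, binWidth = 5000L,
                     config = shapeConfig()) {
  bins <- binCoverage(track, candidate, binWidth = binWidth)
  res <- list(candidate = candidate[c("gene_id", "transcript_id", "chrom",
                                      "rs_position")],
              bins = bins, baseline = NULL, augmented = NULL,
              f_stat = NA_real_, p_value = NA_real_,
              shape_flags = NULL, alpha = alpha, config = config)
  if (bins$status == "insufficient_data") {
    res$verdict <- "insufficient_data"
    return(res)
  }
  base <- fitLinear(bins$x, bins$y)
  aug <- fitLinear(bins$x, bins$y, bins$D)
  ft <- fTest(base, aug)
  flags <- shapeCheck(base, aug, config)
  res$baseline <- base
  res$augmented <- aug
  res$f_stat <- ft$f_stat
  res$p_value <- ft$p_value
  res$shape_flags <- flags
  res$verdict <- if (ft$p_value < alpha && all(flags)) "rs_detected"
                 else "not_detected"
  res
}
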