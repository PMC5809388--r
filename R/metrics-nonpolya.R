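#' Classify transcripts as non-poly(A), poly(A) or unclassified
#'
#' Applies the total-vs-poly(A) differential-fit rules to an upstream
#' differential-expression table (one row per transcript per condition,
#' e.g. ES and PrE):
#' \itemize{
#'   \item \strong{loose} non-poly(A): in at least one condition,
#'     `fdr < 0.05`, the transcript is depleted in the poly(A) library
#'     (`log_fc > 0`, total over poly(A)), and the mean fitted value in the
#'     total library is at least 10;
#'   \item \strong{strict} non-poly(A): loose, and the mean fitted value in
#'     the poly(A) library is below 1 in a qualifying condition;
#'   \item \strong{polyA}: the symmetric loose rule (`fdr < 0.05`, enriched
#'     in poly(A), poly(A) fitted value at least 10);
#'   \item transcripts with assembly class code `"i"` (fully intronic) are
#'     forced to \strong{unclassified}, as they cannot be distinguished from
#'     pre-mRNA.
#' }
#' Strict calls are a subset of loose by construction; the returned label is
#' the strongest applicable one (`strict` > `loose` > `polyA` >
#' `unclassified`).
#'
#' @param deTable data.frame with columns `transcript_id`, `condition`,
#'   `fdr`, `log_fc` (positive = enriched in total RNA-seq), `total_fit`,
#'   `polya_fit`, `class_code`.
#' @return data.frame with `transcript_id` and `label`.
#' @export
classifyNonpolyA <- function(deTable) {
  need <- c("transcript_id", "condition", "fdr", "log_fc", "total_fit",
            "polya_fit", "class_code")
  miss <- setdiff(need, names(deTable))
  if (length(miss))
    stop("de table lacks column(s): ", paste(miss, collapse = ", "))
  loose_row <- deTable$fdr < 0.05 & deTable$log_fc > 0 &
    deTable$total_fit >= 10
  strict_row <- loose_row & deTable$polya_fit < 1
  polya_row <- deTable$fdr < 0.05 & deTable$log_fc < 0 &
    deTable$polya_fit >= 10
  ids <- unique(deTable$transcript_id)
  agg <- function(flag) vapply(ids, function(id)
    any(flag[deTable$transcript_id == id]), logical(1))
  intronic <- vapply(ids, function(id)
    any(deTable$class_code[deTable$transcript_id == id] == "i"), logical(1))
  label <- ifelse(intronic, "unclassified",
           ifelse(agg(strict_row), "strict",
           ifelse(agg(loose_row), "loose",
           ifelse(agg(polya_row), "polyA", "unclassified"))))
  data.frame(transcript_id = ids, label = unname(label),
             stringsAsFactors = FALSE)
}

#' Filter unannotated transcripts near masked annotations
#'
#' Drops assembled transcripts with any exon within `minDist` bp of a masked
#' annotation (tRNA/rRNA/pseudogene intervals) and transcripts whose exonic
#' length is not greater than `minLen` bp.
#'
#' @param transcripts `GRangesList` of exons per transcript.
#' @param masked `GRanges` of masked annotation intervals.
#' @param minDist proximity threshold in bp (drop when gap `< minDist`;
#'   default 100).
#' @param minLen minimum exonic length, strict `>` (default 200).
#' @return the retained `GRangesList`.
#' @export
filterUnannotated <- function(transcripts, masked, minDist = 100L,
                              minLen = 200L) {
  len <- vapply(seq_along(transcripts), function(i)
    sum(GenomicRanges::width(transcripts[[i]])), integer(1))
  keep <- len > minLen
  if (length(masked)) {
    ex <- unlist(transcripts, use.names = FALSE)
    tx_of <- rep(seq_along(transcripts), lengths(transcripts))
    d <- GenomicRanges::distanceToNearest(ex, masked, ignore.strand = TRUE)
    near_ex <- logical(length(ex))
    near_ex[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance < minDist
    near_tx <- vapply(seq_along(transcripts), function(i)
      any(near_ex[tx_of == i]), logical(1))
    keep <- keep & !near_tx
  }
  transcripts[keep]
}

#' Compare per-cell coverage of two regions across cell groups
#'
#' Each region's per-cell mean coverage is first normalized to the average
#' over all cells, then a paired Wilcoxon signed-rank test contrasts the two
#' regions within each cell group (e.g. time point), with Bonferroni
#' correction across groups. Zero-difference pairs are dropped; the exact
#' null distribution is used for n <= 25 pairs, the normal approximation
#' with continuity correction above.
#'
#' @param common,specific per-cell mean coverage of the two regions
#'   (parallel numeric vectors, one entry per cell).
#' @param groups factor of cell groups, parallel to the value vectors.
#' @param minCells groups smaller than this are skipped with a warning
#'   (default 6).
#' @return data.frame with one row per group: `group`, `n_pairs`,
#'   `statistic`, `p_value`, `p_bonferroni`, `direction` (sign of the median
#'   common-minus-specific difference) and `skipped`.
#' @export
compareRegionCoverage <- function(common, specific, groups, minCells = 6L) {
  stopifnot(length(common) == length(specific),
            length(groups) == length(common))
  groups <- as.factor(groups)
  if (mean(common) == 0 || mean(specific) == 0)
    stop("a region has zero coverage in every cell; nothing to compare")
  cn <- common / mean(common)
  sn <- specific / mean(specific)
  lev <- levels(groups)
  res <- lapply(lev, function(g) {
    idx <- groups == g
    if (sum(idx) < minCells) {
      warning("group '", g, "' has fewer than ", minCells,
              " cells; test skipped")
      return(data.frame(group = g, n_pairs = sum(idx), statistic = NA_real_,
                        p_value = NA_real_, p_bonferroni = NA_real_,
                        direction = NA_real_, skipped = TRUE))
    }
    d <- cn[idx] - sn[idx]
    d <- d[d != 0]
    if (!length(d))
      return(data.frame(group = g, n_pairs = 0L, statistic = NA_real_,
                        p_value = 1, p_bonferroni = NA_real_,
                        direction = 0, skipped = FALSE))
    wt <- suppressWarnings(stats::wilcox.test(
      d, exact = length(d) <= 25L, correct = TRUE))
    data.frame(group = g, n_pairs = length(d),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               p_bonferroni = NA_real_, direction = sign(stats::median(d)),
               skipped = FALSE)
  })
  out <- do.call(rbind, res)
  tested <- !out$skipped & !is.na(out$p_value)
  out$p_bonferroni[tested] <- pmin(1, out$p_value[tested] * sum(tested))
  out
}
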