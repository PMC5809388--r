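test_that("3'-end coverage profile matches the definition on one transcript", {
  # 1 000-nt transcript covered only at its 3'-most base, bins of 100
  ex <- GRanges("chr1", IRanges::IRanges(1, 1000), strand = "+")
  txs <- GRangesList(t1 = ex)
  v <- numeric(1000)
  v[1000] <- 4  # 3'-most base on the plus strand
  tr <- makeTrack(v, total = 1e6, normalized = TRUE)
  prof <- coverageProfile3p(txs, tr, binEdges = seq(0, 1000, by = 100))
  expect_equal(prof$fraction[1], 1)
  expect_equal(prof$fraction[-1], rep(0, 9))
  # transcripts shorter than the bin edge drop out of the denominator
  prof2 <- coverageProfile3p(txs, tr, binEdges = c(0, 500, 1500, 2500))
  expect_equal(prof2$N, c(1, 1, 0))
  expect_error(coverageProfile3p(GRangesList(), tr), "empty")
})

test_that("3'-end coverage profile matches brute force on three transcripts", {
  # three plus/minus transcripts with two exons each over one track
  txs <- GRangesList(
    a = GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 400)),
                strand = "+"),
    b = GRanges("chr1", IRanges::IRanges(c(501, 801), c(700, 900)),
                strand = "-"),
    c = GRanges("chr1", IRanges::IRanges(1001, 1600), strand = "+"))
  set.seed(8)
  v <- rbinom(1600, 1, 0.02) * sample(1:3, 1600, replace = TRUE)
  tr <- makeTrack(v, total = 1e6, normalized = TRUE)
  edges <- c(0, 50, 150, 300, 700)
  prof <- coverageProfile3p(txs, tr, binEdges = edges)
  # independent brute force: enumerate covered distances per transcript
  dists <- lapply(txs, function(ex) {
    idx <- unlist(lapply(seq_along(ex), function(j)
      seq(start(ex[j]), end(ex[j]))))
    cov <- v[idx] > 0
    if (as.character(strand(ex))[1] != "-") cov <- rev(cov)
    which(cov) - 1L
  })
  lens <- vapply(dists, function(d) NA_integer_, integer(1))
  lens <- vapply(txs, function(ex) sum(width(ex)), integer(1))
  for (i in seq_len(length(edges) - 1)) {
    N <- sum(lens >= edges[i])
    n <- sum(vapply(dists, function(d)
      any(d >= edges[i] & d < edges[i + 1]), logical(1)))
    expect_equal(prof$n[i], n)
    expect_equal(prof$N[i], N)
  }
})

test_that("exonic covered fraction counts bases with any read", {
  ex <- GRanges("chr1", IRanges::IRanges(1, 100))
  v <- numeric(100); v[1:50] <- 2
  expect_equal(exonicFractionCovered(ex, makeTrack(v, total = 1e6)), 0.5)
  expect_equal(exonicFractionCovered(ex, makeTrack(numeric(100),
                                                   total = 1e6)), 0)
  expect_equal(exonicFractionCovered(ex, makeTrack(rep(1, 100),
                                                   total = 1e6)), 1)
  expect_error(exonicFractionCovered(GRanges(), makeTrack(v, total = 1e6)),
               "zero")
})

test_that("enhancer filtering enforces the 2-kb gap and 400-bp width", {
  gene <- GRangesList(t1 = GRanges("chr1", IRanges::IRanges(10000, 12000),
                                   strand = "+"))
  S4Vectors::mcols(gene)$gene_id <- "g1"
  enh <- GRanges("chr1", IRanges::IRanges(
    c(13999, 14001, 30000, 50000),
    c(13999 + 199, 14001 + 199, 30400, 50199)))
  # gaps to the gene end (12000): 1998 bp, 2000 bp; widths 200/200/401/200
  out <- filterEnhancers(enh, gene)
  expect_equal(start(out), c(14001, 50000))
  w <- out[1]
  expect_equal(S4Vectors::mcols(w)$window_end -
                 S4Vectors::mcols(w)$window_start + 1L, 801L)
})

test_that("feature detection is strict at the threshold", {
  counts <- c(f1 = 15, f2 = 10, f3 = 0)
  det <- detectFeatures(counts, totalMapped = 1e8, threshold = 0.1)
  expect_equal(det$normalized_value, c(0.15, 0.10, 0))
  expect_identical(det$detected, c(TRUE, FALSE, FALSE))  # 0.1 is NOT > 0.1
  expect_error(detectFeatures(counts, 0), "positive")
})

test_that("enhancer aggregation normalizes, trims and averages per bin", {
  set.seed(31)
  n_enh <- 10
  flank <- 500L
  profiles <- matrix(runif(n_enh * 2 * flank, 0, 2), nrow = n_enh)
  profiles[1, ] <- 0.001    # weakly expressed: filtered by the top-70% rule
  profiles[2, ] <- 0.001
  profiles[3, ] <- 0.001
  agg <- aggregateEnhancerProfile(profiles, bin = 50L, trimTop = 0.01,
                                  keepTopExpr = 0.70)
  # brute force: same recipe by hand
  rel <- seq(-flank, flank - 1) + 0.5
  score <- rowSums(profiles[, abs(rel) >= 75 & abs(rel) <= 275])
  keep <- score >= quantile(score, 0.30)
  P <- profiles[keep, ]
  P <- P / rowSums(P)
  k <- floor(nrow(P) * 0.01)  # 0 here: trimming is vacuous at n = 7
  means <- sapply(seq_len(ncol(P) / 50), function(i)
    mean(P[, ((i - 1) * 50 + 1):(i * 50)] %*% rep(1, 50)))
  expect_equal(agg$mean, means, tolerance = 1e-12)
  # each retained profile sums to 1, so bin means are a convex combination
  expect_equal(sum(agg$mean), 1, tolerance = 1e-12)
  expect_true(all(agg$mean >= 0))
  expect_equal(unique(agg$n_enhancers), nrow(P))

  # single enhancer: the aggregate is its own normalized profile
  one <- matrix(runif(1000, 0, 1), nrow = 1)
  agg1 <- aggregateEnhancerProfile(one, bin = 50L)
  o <- one / sum(one)
  expect_equal(agg1$mean, as.numeric(sapply(seq_len(20), function(i)
    sum(o[((i - 1) * 50 + 1):(i * 50)]))), tolerance = 1e-12)
})

test_that("trimming drops the top fraction of enhancers per bin", {
  set.seed(5)
  profiles <- matrix(rexp(200 * 400), nrow = 200)
  agg <- aggregateEnhancerProfile(profiles, bin = 50L, trimTop = 0.05,
                                  keepTopExpr = 1.0)
  P <- profiles / rowSums(profiles)
  k <- floor(200 * 0.05)
  hand <- sapply(seq_len(8), function(i) {
    b <- P[, ((i - 1) * 50 + 1):(i * 50)] %*% rep(1, 50)
    mean(sort(b)[1:(200 - k)])
  })
  expect_equal(agg$mean, as.numeric(hand), tolerance = 1e-12)
  expect_true(sum(agg$mean) <= 1 + 1e-12)
})

test_that("histone-mark ratio gates eRNAs with a pseudocount fallback", {
  # normalized: me1 = 3, me3 = 2 -> log2(1.5) = 0.585 > 0.58 -> kept
  r <- histoneErnaFilter(c(a = 3, b = 2, c = 1, d = 0),
                         c(a = 2, b = 2, c = 0, d = 2),
                         me1Total = 1e6, me3Total = 1e6)
  expect_true(r$is_eRNA[1])
  expect_equal(r$log2_ratio[1], log2(1.5), tolerance = 1e-12)
  expect_false(r$is_eRNA[2])   # equal marks: ratio 0
  expect_true(r$pseudo_used[3])
  expect_true(is.finite(r$log2_ratio[3]))
  expect_true(r$pseudo_used[4])
})

test_that("non-poly(A) classification follows the printed thresholds", {
  de <- data.frame(
    transcript_id = c("strict", "loose", "intronic", "pa", "none"),
    condition = "ES",
    fdr = c(0.01, 0.01, 0.01, 0.01, 0.5),
    log_fc = c(1, 1, 1, -1, 1),
    total_fit = c(12, 12, 12, 3, 12),
    polya_fit = c(0.4, 2.0, 0.4, 15, 0.4),
    class_code = c("u", "u", "i", "u", "u"),
    stringsAsFactors = FALSE)
  lab <- classifyNonpolyA(de)
  expect_equal(lab$label[lab$transcript_id == "strict"], "strict")
  expect_equal(lab$label[lab$transcript_id == "loose"], "loose")
  expect_equal(lab$label[lab$transcript_id == "intronic"], "unclassified")
  expect_equal(lab$label[lab$transcript_id == "pa"], "polyA")
  expect_equal(lab$label[lab$transcript_id == "none"], "unclassified")
  expect_error(classifyNonpolyA(de[, -3]), "lacks column")
})

test_that("strict non-poly(A) calls are a subset of loose on random tables", {
  set.seed(17)
  de <- data.frame(
    transcript_id = rep(sprintf("t%03d", 1:150), each = 2),
    condition = rep(c("ES", "PrE"), 150),
    fdr = runif(300),
    log_fc = rnorm(300),
    total_fit = rexp(300, 1 / 20),
    polya_fit = rexp(300, 1 / 5),
    class_code = sample(c("u", "x", "i", "j"), 300, replace = TRUE),
    stringsAsFactors = FALSE)
  lab <- classifyNonpolyA(de)
  loose_de <- de
  # a strict call under the same table must also satisfy the loose rule:
  # recompute labels with the strict requirement disabled
  strict_ids <- lab$transcript_id[lab$label == "strict"]
  for (id in strict_ids) {
    rows <- de[de$transcript_id == id, ]
    expect_true(any(rows$fdr < 0.05 & rows$log_fc > 0 &
                      rows$total_fit >= 10))
  }
})

test_that("unannotated-transcript filters apply the printed distances", {
  masked <- GRanges("chr1", IRanges::IRanges(5000, 5100))
  mk <- function(s, e) GRanges("chr1", IRanges::IRanges(s, e), strand = "+")
  txs <- GRangesList(near = mk(4600, 4901),       # 99 bp gap by boundaries
                     short = mk(20000, 20199),    # exactly 200 nt
                     clean = mk(30000, 30299))    # 300 nt, far away
  out <- filterUnannotated(txs, masked)
  expect_identical(names(out), "clean")
})

test_that("two-region comparison normalizes, tests and corrects per group", {
  set.seed(23)
  groups <- rep(c("00h", "12h", "24h", "48h"), each = 12)
  common <- rlnorm(48, log(10), 0.4)
  specific <- rlnorm(48, log(10), 0.4)
  specific[groups == "12h"] <- specific[groups == "12h"] * 0.05
  res <- compareRegionCoverage(common, specific, groups)
  expect_equal(nrow(res), 4)
  sig <- res$p_bonferroni < 0.05
  expect_true(sig[res$group == "12h"])
  expect_false(any(sig[res$group != "12h"]))
  # after normalization the 12h cells have relatively LOW specific signal
  expect_equal(res$direction[res$group == "12h"], 1)

  # identical regions: all pairs tie out, p = 1
  same <- compareRegionCoverage(common, common, groups)
  expect_true(all(same$p_value == 1))

  # small groups are skipped with a warning
  expect_warning(
    res2 <- compareRegionCoverage(common[1:10], specific[1:10],
                                  rep(c("a", "b"), c(8, 2))),
    "fewer than")
  expect_true(res2$skipped[res2$group == "b"])

  # all-zero coverage cannot be normalized
  expect_error(compareRegionCoverage(numeric(10), rexp(10), rep("a", 10)),
               "zero coverage")
})

test_that("small groups use the exact signed-rank null distribution", {
  common <- c(10, 11, 12, 13, 14, 15, 16, 17)
  specific <- c(2, 3, 2.5, 4, 3.5, 5, 4.5, 6)
  res <- compareRegionCoverage(common, specific, rep("g", 8))
  d <- common / mean(common) - specific / mean(specific)
  d <- d[d != 0]
  w <- wilcox.test(d, exact = TRUE)
  expect_equal(res$p_value, w$p.value)
  expect_equal(res$statistic, unname(w$statistic))
})
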