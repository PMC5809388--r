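test_that("locus specs validate their recursive-site geometry", {
  expect_error(locusSpec("normal",
                         rsSites = data.frame(position = 1000L,
                                              type = "five_prime")),
               "empty")
  expect_error(locusSpec("recursive",
                         rsSites = data.frame(position = 2000L,
                                              type = "five_prime")),
               "5 kb")
})

test_that("planted motifs pass the candidate motif filters by construction", {
  for (st in c("+", "-")) {
    locus <- locusSpec("recursive", strand = st)
    gen <- simulateGenome(locus, seed = 5)
    cut <- gen$truth$rs_genomic[1]
    win <- if (st == "-") c(cut - 4L, cut) else c(cut + 1L, cut + 5L)
    s <- Biostrings::subseq(gen$genome[[locus$chrom]], win[1], win[2])
    if (st == "-") s <- Biostrings::reverseComplement(s)
    expect_true(has5ssMotif(as.character(s)))
  }
  locus3 <- locusSpec("recursive",
                      rsSites = data.frame(position = 150000L,
                                           type = "three_prime"))
  gen3 <- simulateGenome(locus3, seed = 6)
  cut <- gen3$truth$rs_genomic[1]
  w <- as.character(Biostrings::subseq(gen3$genome[[1]], cut - 21L, cut))
  expect_true(has3ssMotif(w)$passes)
})

test_that("expected profiles follow the closed forms", {
  # normal mode, floor 0: a straight line hitting 0 at the intron end
  locus0 <- locusSpec("normal", decayFloor = 0)
  p0 <- expectedIntronProfile(locus0)
  intr <- p0[(locus0$exonLength + 1):(locus0$exonLength +
                                        locus0$intronLength)]
  expect_equal(intr[1], 1)
  expect_equal(intr[length(intr)], 0, tolerance = 1e-5)
  d <- diff(intr)
  expect_equal(max(abs(d - d[1])), 0, tolerance = 1e-12)  # constant slope
  # exons sit at the plateau
  expect_equal(p0[1], locus0$exonPlateau)

  # one RS site at the midpoint: two identical descending ramps
  locus <- locusSpec("recursive")
  p <- expectedIntronProfile(locus)
  intr <- p[(locus$exonLength + 1):(locus$exonLength + locus$intronLength)]
  half <- locus$intronLength / 2
  expect_equal(intr[1:half], intr[(half + 1):(2 * half)], tolerance = 1e-12)
  expect_equal(intr[1], 1)

  expect_error(expectedIntronProfile(locusSpec("unexpressed")), "no coverage")
})

test_that("noiseless binned fit recovers the planted ramp height", {
  locus <- locusSpec("recursive")
  cand <- standardCandidate(locus)
  p <- expectedIntronProfile(locus)
  tr <- makeTrack(c(numeric(locus$flank), p, numeric(locus$flank)),
                  chrom = locus$chrom, total = 1e6, normalized = TRUE)
  b <- binCoverage(tr, cand)
  aug <- fitLinear(b$x, b$y, b$D)
  step_per_base <- (1 - locus$decayFloor) / 2
  expect_equal(-aug$beta2, 5000 * step_per_base, tolerance = 1e-6)
  expect_lt(aug$rss / sum(b$y^2), 1e-20)
})

test_that("simulated per-base counts conserve the expected profile", {
  locus <- locusSpec("recursive", intronLength = 30000L, exonLength = 200L,
                     flank = 100L,
                     rsSites = data.frame(position = 15000L,
                                          type = "five_prime"))
  cfg <- simConfig(nCells = 60, depthMeanLog = log(0.5), depthSdLog = 0.3,
                   seed = 99)
  sim <- simulateCells(locus, cfg)
  pooled <- Reduce(`+`, lapply(sim$tracks, function(t)
    as.numeric(trackValues(t)[[1]])))
  depth_tot <- sum(sim$depths$depth)
  p <- expectedIntronProfile(locus)
  lam <- c(numeric(locus$flank), p, numeric(locus$flank)) * depth_tot
  # aggregate over 500-bp windows: every window within 4 SEs of expectation
  w <- 500
  m <- matrix(pooled[1:(w * (length(lam) %/% w))], nrow = w)
  lm_ <- matrix(lam[1:(w * (length(lam) %/% w))], nrow = w)
  obs <- colSums(m); expc <- colSums(lm_)
  z <- (obs - expc) / sqrt(pmax(expc, 1))
  expect_lt(max(abs(z)), 4)
})

test_that("simulation outputs are byte-identical under one seed", {
  locus <- locusSpec("recursive", intronLength = 30000L, exonLength = 200L,
                     flank = 100L,
                     rsSites = data.frame(position = 15000L,
                                          type = "five_prime"))
  run <- function(dir) {
    gen <- simulateGenome(locus, seed = 7)
    sim <- simulateCells(locus, simConfig(nCells = 5, seed = 8))
    writeSimulation(locus, sim, gen, dir)
    dir
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run(d1); run(d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("unexpressed cells produce all-zero tracks", {
  locus <- locusSpec("unexpressed", intronLength = 30000L,
                     exonLength = 200L, flank = 100L)
  sim <- simulateCells(locus, simConfig(nCells = 2, seed = 3))
  expect_true(all(vapply(sim$tracks, function(t)
    sum(trackValues(t)[[1]]) == 0, logical(1))))
  expect_error(simulateCells(locus, simConfig(nCells = 0, seed = 3)),
               "positive")
})

test_that("enhancer cohort shows bimodal flanks and truth-linked detection", {
  sim <- simulateEnhancerCohort(seed = 41)
  profiles <- enhancerProfileMatrix(
    lapply(sim$tracks, normalizeByDepth), sim$enhancers, flank = 1000L)
  act <- profiles[sim$truth$active, , drop = FALSE]
  agg <- aggregateEnhancerProfile(act, bin = 50L)
  expect_equal(sum(agg$mean), 1, tolerance = 1e-9)
  mids <- (agg$pos_lo + agg$pos_hi) / 2
  # two local maxima flanking the center: peaks in each half away from it
  left <- agg$mean[mids < 0]; right <- agg$mean[mids > 0]
  peak_l <- mids[mids < 0][which.max(left)]
  peak_r <- mids[mids > 0][which.max(right)]
  expect_true(peak_l < -100 && peak_l > -500)
  expect_true(peak_r > 100 && peak_r < 500)
  center_level <- agg$mean[abs(mids) < 100]
  expect_gt(max(left), max(center_level))

  # detection: active enhancers fire, inactive stay near background
  det_rate <- function(idx) {
    hits <- vapply(seq_along(sim$totals), function(c_)
      detectFeatures(sim$windowCounts[idx, c_], sim$totals[c_])$detected,
      logical(length(which(idx))))
    mean(hits)
  }
  expect_gt(det_rate(sim$truth$active), 0.8)
  expect_lt(det_rate(!sim$truth$active), 0.2)
})

test_that("end-to-end truth recovery on the standard three-locus design", {
  seeds <- c(101, 202)
  for (s in seeds) {
    locus_rs <- locusSpec("recursive")
    gen <- simulateGenome(locus_rs, seed = s)
    sim <- simulateCells(locus_rs, simConfig(nCells = 30, seed = s + 1))
    cand <- findRsCandidates(sim$junctions, gen$transcripts, gen$genome)
    expect_equal(nrow(cand), 1)
    pooled <- sumTracks(lapply(sim$tracks, normalizeByDepth))
    expect_equal(detectRs(pooled, cand[1, ])$verdict, "rs_detected")

    locus_n <- locusSpec("normal")
    sim_n <- simulateCells(locus_n, simConfig(nCells = 30, seed = s + 2))
    pooled_n <- sumTracks(lapply(sim_n$tracks, normalizeByDepth))
    expect_equal(detectRs(pooled_n, cand[1, ])$verdict, "not_detected")

    locus_u <- locusSpec("unexpressed")
    sim_u <- simulateCells(locus_u, simConfig(nCells = 5, seed = s + 3))
    pooled_u <- sumTracks(lapply(sim_u$tracks, normalizeByDepth))
    expect_equal(detectRs(pooled_u, cand[1, ])$verdict, "insufficient_data")
  }
})
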