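# Shared fixture builders: everything is constructed in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# A single-region track on chr/strand with the given per-base values.
makeTrack <- function(values, chrom = "chr1", start = 1L, strand = "+",
                      total = 1e6, cellId = "cellA", normalized = FALSE) {
  gr <- GRanges(chrom, IRanges::IRanges(start, start + length(values) - 1L),
                strand = strand)
  CoverageTrack(cellId, gr, values, total, normalized = normalized)
}

# A candidate row without running junction discovery (geometry only).
makeCandidate <- function(chrom = "chr1", intron_start = 1L,
                          intron_end = 300000L, strand = "+",
                          rs_position = 150000L) {
  data.frame(gene_id = "g1", transcript_id = "t1", chrom = chrom,
             intron_start = intron_start, intron_end = intron_end,
             strand = strand, rs_position = rs_position,
             rs_genomic = NA_integer_, side = "five_prime",
             known_side = "acceptor", motif = "GTAAG",
             pyrimidine_count = NA_integer_, read_count = 10L,
             max_overhang = 30L, stringsAsFactors = FALSE)
}

# Brute-force OLS oracle: explicit normal equations + ANOVA F decomposition,
# independent of fitLinear()/fTest().
oracleOls <- function(x, y, D = NULL) {
  X <- if (is.null(D)) cbind(1, x) else cbind(1, x, D)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  r <- y - X %*% beta
  rss <- sum(r^2)
  df <- length(y) - ncol(X)
  s2 <- rss / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(beta = as.numeric(beta), se = as.numeric(se), rss = rss, df = df)
}

oracleF <- function(x, y, D) {
  o0 <- oracleOls(x, y)
  o1 <- oracleOls(x, y, D)
  f <- ((o0$rss - o1$rss) / 1) / (o1$rss / o1$df)
  list(f = f, p = pf(f, 1, o1$df, lower.tail = FALSE))
}

# Toy single-gene annotation with one long intron, plus genome with planted
# motifs; returns everything needed for candidate-filter tests.
toyRsLocus <- function(strand = "+", intron_len = 200000L,
                       exon_len = 1000L, rs_pos = 100000L, seed = 42L) {
  locus <- locusSpec(mode = "recursive", intronLength = intron_len,
                     exonLength = exon_len,
                     rsSites = data.frame(position = rs_pos,
                                          type = "five_prime",
                                          stringsAsFactors = FALSE),
                     strand = strand, chrom = "chrT")
  gen <- simulateGenome(locus, seed = seed)
  istart <- locus$flank + exon_len + 1L
  iend <- istart + intron_len - 1L
  cut <- gen$truth$rs_genomic[1L]
  minus <- strand == "-"
  # second planted donor used by the short-span junction (4 900-bp span)
  cut2 <- if (minus) istart + 4899L else iend - 4900L
  seq <- gen$genome[[1L]]
  if (minus)
    Biostrings::subseq(seq, cut2 - 4L, cut2) <- Biostrings::DNAString("CTTAC")
  else
    Biostrings::subseq(seq, cut2 + 1L, cut2 + 5L) <-
      Biostrings::DNAString("GTAAG")
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chrT"
  list(locus = locus, genome = genome, transcripts = gen$transcripts,
       istart = istart, iend = iend, cut = cut, cut2 = cut2)
}

# The hand-enumerable junction table for the toy locus: junction "pass"
# survives all five candidate filters, every other junction violates exactly
# one of them.
toyJunctions <- function(fx) {
  minus <- as.character(strand(fx$transcripts[[1]]))[1] == "-"
  jx <- function(start, end, status, side, overhang = 30L, reads = 5L)
    data.frame(chrom = "chrT", start = start, end = end,
               strand = if (minus) "-" else "+", read_count = reads,
               max_overhang = overhang, anchor_status = status,
               known_side = side, stringsAsFactors = FALSE)
  # novel donor at the cut, known acceptor at the intron 3' end
  if (!minus) {
    pass <- jx(fx$cut + 1L, fx$iend, "partially_novel", "acceptor")
    low_overhang <- jx(fx$cut + 1L, fx$iend, "partially_novel", "acceptor",
                       overhang = 10L)
    short_span <- jx(fx$iend - 4899L, fx$iend, "partially_novel", "acceptor")
    annotated <- jx(fx$istart, fx$iend, "both_known", "none")
    no_motif <- jx(fx$cut + 5001L, fx$iend, "partially_novel", "acceptor")
    near_edge <- jx(fx$istart + 4000L, fx$iend, "partially_novel", "acceptor")
  } else {
    pass <- jx(fx$istart, fx$cut, "partially_novel", "acceptor")
    low_overhang <- jx(fx$istart, fx$cut, "partially_novel", "acceptor",
                       overhang = 10L)
    short_span <- jx(fx$istart, fx$istart + 4899L, "partially_novel",
                     "acceptor")
    annotated <- jx(fx$istart, fx$iend, "both_known", "none")
    no_motif <- jx(fx$istart, fx$cut - 5001L, "partially_novel", "acceptor")
    near_edge <- jx(fx$istart, fx$iend - 4000L, "partially_novel",
                    "acceptor")
  }
  rbind(pass, low_overhang, short_span, annotated, no_motif, near_edge)
}

# Pooled-coverage track for one locus simulated directly at pooled depth
# (per-base Poisson around the expected shape), in raw counts.
simulatePooledTrack <- function(locus, depth, seed,
                                total = 4e8) {
  set.seed(seed)
  p <- expectedIntronProfile(locus)
  if (locus$strand == "-") p <- rev(p)
  lam <- c(numeric(locus$flank), p, numeric(locus$flank)) * depth
  makeTrack(rpois(length(lam), lam), chrom = locus$chrom,
            strand = locus$strand, total = total, cellId = "pool")
}

standardCandidate <- function(locus = locusSpec("recursive")) {
  istart <- locus$flank + locus$exonLength + 1L
  makeCandidate(chrom = locus$chrom, intron_start = istart,
                intron_end = istart + locus$intronLength - 1L,
                strand = locus$strand,
                rs_position = locus$intronLength %/% 2L)
}
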