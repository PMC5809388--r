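#' Specification of a simulated long-intron locus
#'
#' Describes a two-exon gene whose single long intron either undergoes
#' recursive splicing (`recursive`: the nascent-coverage ramp resets at each
#' RS site), splices normally (`normal`: one monotone linear decay across
#' the intron), or is not expressed. The intronic decay emulates nascent
#' transcription: coverage declines linearly from 1 at the intron 5' end at
#' a per-bp slope of `(1 - decayFloor) / intronLength`; in recursive mode
#' the ramp restarts at 1 at every RS site. Exon bases sit at a plateau
#' above the intron (`exonPlateau`).
#'
#' @param mode `"recursive"`, `"normal"` or `"unexpressed"`.
#' @param intronLength intron length in bp (default 300 kb).
#' @param exonLength flanking exon length in bp.
#' @param rsSites data.frame with `position` (transcription-direction bp
#'   from the intron 5' end) and `type` (`"five_prime"` or `"three_prime"`,
#'   the motif planted at the site). Default: one five-prime site at the
#'   intron midpoint for `recursive` mode, none otherwise.
#' @param strand `"+"` or `"-"`.
#' @param chrom chromosome name of the simulated contig.
#' @param flank untranscribed sequence padding each side, bp.
#' @param decayFloor relative coverage remaining at the 3' end of a normal
#'   intron (default 0.25).
#' @param exonPlateau relative exon coverage level (default 3).
#' @param geneId,transcriptId feature names.
#' @return list of class `locusSpec`.
#' @export
locusSpec <- function(mode = c("recursive", "normal", "unexpressed"),
                      intronLength = 300000L, exonLength = 1000L,
                      rsSites = NULL, strand = "+", chrom = "chrS",
                      flank = 500L, decayFloor = 0.25, exonPlateau = 3,
                      geneId = "geneS", transcriptId = "geneS.1") {
  mode <- match.arg(mode)
  if (is.null(rsSites))
    rsSites <- if (mode == "recursive")
      data.frame(position = intronLength %/% 2L, type = "five_prime",
                 stringsAsFactors = FALSE)
    else data.frame(position = integer(), type = character(),
                    stringsAsFactors = FALSE)
  if (mode != "recursive" && nrow(rsSites))
    stop("rsSites must be empty unless mode is 'recursive'")
  if (nrow(rsSites) &&
      any(rsSites$position < 5000L |
          rsSites$position > intronLength - 5000L))
    stop("RS sites must be > 5 kb from both intron boundaries")
  structure(list(mode = mode, intronLength = as.integer(intronLength),
                 exonLength = as.integer(exonLength),
                 rsSites = rsSites[order(rsSites$position), , drop = FALSE],
                 strand = strand, chrom = chrom, flank = as.integer(flank),
                 decayFloor = decayFloor, exonPlateau = exonPlateau,
                 geneId = geneId, transcriptId = transcriptId),
            class = "locusSpec")
}

# Genomic layout of the locus (1-based inclusive coordinates).
.locusLayout <- function(locus) {
  e1s <- locus$flank + 1L
  e1e <- e1s + locus$exonLength - 1L
  is_ <- e1e + 1L
  ie <- is_ + locus$intronLength - 1L
  e2s <- ie + 1L
  e2e <- e2s + locus$exonLength - 1L
  list(exon1 = c(e1s, e1e), intron = c(is_, ie), exon2 = c(e2s, e2e),
       span = e2e + locus$flank)
}

#' Transcript annotation of a simulated locus
#'
#' @param locus a [locusSpec()].
#' @return `GRangesList` with one transcript (its two exons) in the format
#'   of [readGtf()].
#' @export
locusTranscripts <- function(locus) {
  lay <- .locusLayout(locus)
  ex <- GenomicRanges::GRanges(locus$chrom,
    IRanges::IRanges(c(lay$exon1[1L], lay$exon2[1L]),
                     c(lay$exon1[2L], lay$exon2[2L])),
    strand = locus$strand)
  out <- GenomicRanges::GRangesList(ex)
  names(out) <- locus$transcriptId
  S4Vectors::mcols(out)$gene_id <- locus$geneId
  out
}

#' Simulate the genome sequence of a locus
#'
#' Random background sequence with exact splice-motif windows planted at the
#' RS sites: a whitelist pentamer immediately downstream of a `five_prime`
#' site, a passing 22-mer polypyrimidine window (ending in TAG) immediately
#' upstream of a `three_prime` site, both in transcription orientation.
#' Canonical GT/AG dinucleotides are planted at the host intron boundaries.
#'
#' @param locus a [locusSpec()].
#' @param seed integer seed.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `transcripts`
#'   (as [locusTranscripts()]) and `truth` (data.frame with `mode` and RS
#'   positions/types/genomic cut points).
#' @export
simulateGenome <- function(locus, seed) {
  lay <- .locusLayout(locus)
  set.seed(seed)
  seq <- sample(c("A", "C", "G", "T"), lay$span, replace = TRUE)
  minus <- locus$strand == "-"
  plant <- function(chars, gstart) {
    # chars are transcription-orientation; place on the genome
    if (minus) chars <- rev(chartr("ACGT", "TGCA", chars))
    seq[seq.int(gstart, gstart + length(chars) - 1L)] <<- chars
  }
  # canonical boundaries of the host intron (donor GT ... AG acceptor)
  don <- strsplit("GTAAG", "")[[1L]]
  acc <- strsplit("AG", "")[[1L]]
  if (!minus) {
    plant(don, lay$intron[1L])
    plant(acc, lay$intron[2L] - 1L)
  } else {
    plant(don, lay$intron[2L] - 4L)
    plant(acc, lay$intron[1L])
  }
  cuts <- integer(nrow(locus$rsSites))
  for (i in seq_len(nrow(locus$rsSites))) {
    pos <- locus$rsSites$position[i]
    cut <- if (minus) lay$intron[2L] - pos else lay$intron[1L] - 1L + pos
    cuts[i] <- cut
    if (locus$rsSites$type[i] == "five_prime") {
      pent <- strsplit("GTAAG", "")[[1L]]
      plant(pent, if (minus) cut - 4L else cut + 1L)
    } else {
      win <- c(sample(c("C", "T"), 19L, replace = TRUE), "T", "A", "G")
      plant(win, if (minus) cut + 1L else cut - 21L)
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- locus$chrom
  truth <- data.frame(gene_id = locus$geneId, mode = locus$mode,
                      rs_position = if (nrow(locus$rsSites))
                        locus$rsSites$position else NA_integer_,
                      rs_type = if (nrow(locus$rsSites))
                        locus$rsSites$type else NA_character_,
                      rs_genomic = if (length(cuts)) cuts else NA_integer_,
                      stringsAsFactors = FALSE)
  list(genome = genome, transcripts = locusTranscripts(locus), truth = truth)
}

#' Expected per-base coverage shape of a locus
#'
#' Closed-form relative coverage in transcription orientation over the
#' transcript span (exon 1, intron, exon 2). Normal mode: linear decay from
#' 1 at the intron 5' end to `decayFloor` at its 3' end. Recursive mode: the
#' same per-bp slope, resetting to 1 at every RS site (sawtooth). Exons sit
#' at `exonPlateau`.
#'
#' @param locus a [locusSpec()]; mode must not be `"unexpressed"`.
#' @param mode optional override of the locus mode (handy for simulating
#'   mixed-mode cells on one locus geometry).
#' @return numeric vector of length `2 * exonLength + intronLength`.
#' @export
expectedIntronProfile <- function(locus, mode = locus$mode) {
  if (mode == "unexpressed") stop("unexpressed locus has no coverage shape")
  L <- locus$intronLength
  slope <- (1 - locus$decayFloor) / L
  pos <- seq_len(L)  # transcription-direction bp, base i covers (i-1, i]
  starts <- if (mode == "recursive") c(0L, locus$rsSites$position) else 0L
  seg_start <- starts[findInterval(pos - 1L, starts)]
  intron <- 1 - slope * (pos - 1L - seg_start)
  c(rep(locus$exonPlateau, locus$exonLength), intron,
    rep(locus$exonPlateau, locus$exonLength))
}

#' Simulation configuration for a per-cell coverage cohort
#'
#' Per-cell sequencing depth is log-normal: cell `c` has expected per-base
#' coverage `depth_c` at the intron-5' ramp start, with
#' `log(depth_c) ~ N(depthMeanLog, depthSdLog^2)`; per-base counts are
#' Poisson with mean `depth_c *` the locus shape. Mapped-read totals scale
#' with depth around `totalReadsBase`.
#'
#' @param nCells number of cells (default 100).
#' @param depthMeanLog,depthSdLog log-normal depth parameters (defaults
#'   `log(0.03)` and 1, i.e. a median cell has ~0.03x per-base coverage at
#'   the ramp start, emulating a moderately expressed host gene at a few
#'   million reads per cell).
#' @param readLength sequencing read length, nt (default 76).
#' @param totalReadsBase mapped-read total of a median-depth cell.
#' @param seed mandatory integer seed.
#' @return list of class `simConfig`.
#' @export
simConfig <- function(nCells = 100L, depthMeanLog = log(0.03),
                      depthSdLog = 1, readLength = 76L,
                      totalReadsBase = 4e6, seed) {
  if (missing(seed)) stop("simConfig requires an explicit seed")
  stopifnot(nCells >= 0, depthSdLog >= 0, readLength > 0, totalReadsBase > 0)
  structure(list(nCells = as.integer(nCells), depthMeanLog = depthMeanLog,
                 depthSdLog = depthSdLog, readLength = as.integer(readLength),
                 totalReadsBase = totalReadsBase, seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate a per-cell coverage cohort over one locus
#'
#' Draws per-cell depths, Poisson per-base counts along the locus's expected
#' shape, splice-junction records with anchor truth, and per-cell
#' mapped-read totals. Everything is deterministic given `config$seed`.
#'
#' @param locus a [locusSpec()].
#' @param config a [simConfig()].
#' @param modes optional per-cell mode override (character vector of length
#'   `nCells` over `"recursive"`, `"normal"`, `"unexpressed"`); default all
#'   cells follow `locus$mode`. Junction records reflect the locus-level
#'   truth.
#' @return list with `tracks` (list of raw [CoverageTrack-class], one per
#'   cell, covering the whole simulated contig), `junctions` (data.frame in
#'   the [readJunctions()] convention), `depths` (data.frame `cell_id`,
#'   `total_mapped_reads`, `depth`, `mode`), and `truth`.
#' @export
simulateCells <- function(locus, config, modes = NULL) {
  if (config$nCells == 0L) stop("nCells must be positive")
  if (is.null(modes)) modes <- rep(locus$mode, config$nCells)
  stopifnot(length(modes) == config$nCells,
            all(modes %in% c("recursive", "normal", "unexpressed")))
  lay <- .locusLayout(locus)
  region <- GenomicRanges::GRanges(locus$chrom,
                                   IRanges::IRanges(1L, lay$span))
  minus <- locus$strand == "-"
  shape_of <- function(m) {
    if (m == "unexpressed") return(numeric(lay$span))
    p <- expectedIntronProfile(locus, mode = m)
    if (minus) p <- rev(p)
    c(numeric(locus$flank), p, numeric(locus$flank))
  }
  shapes <- list(recursive = NULL, normal = NULL, unexpressed = NULL)
  set.seed(config$seed)
  depths <- stats::rlnorm(config$nCells, config$depthMeanLog,
                          config$depthSdLog)
  cell_ids <- sprintf("cell%03d", seq_len(config$nCells))
  tracks <- vector("list", config$nCells)
  for (c_ in seq_len(config$nCells)) {
    m <- modes[c_]
    if (is.null(shapes[[m]])) shapes[[m]] <- shape_of(m)
    lam <- shapes[[m]] * depths[c_]
    tracks[[c_]] <- CoverageTrack(cell_ids[c_], region,
      stats::rpois(lay$span, lam),
      max(1, round(config$totalReadsBase * depths[c_] /
                     exp(config$depthMeanLog))))
  }
  names(tracks) <- cell_ids
  # junction records: annotated host intron + one truth junction per RS site
  istart <- lay$intron[1L]; iend <- lay$intron[2L]
  jx <- list(data.frame(chrom = locus$chrom, start = istart, end = iend,
                        strand = locus$strand,
                        read_count = max(1L, stats::rpois(1L,
                          20 * sum(depths))),
                        max_overhang = config$readLength - 10L,
                        anchor_status = "both_known", known_side = "none",
                        stringsAsFactors = FALSE))
  for (i in seq_len(nrow(locus$rsSites))) {
    pos <- locus$rsSites$position[i]
    cut <- if (minus) iend - pos else istart - 1L + pos
    five <- locus$rsSites$type[i] == "five_prime"
    # five_prime: novel donor at the cut, known acceptor at the intron 3' end;
    # three_prime: known donor at the intron 5' end, novel acceptor at the cut
    if (five == !minus) { jstart <- cut + 1L; jend <- iend }
    else { jstart <- istart; jend <- cut }
    nreads <- max(2L, stats::rpois(1L, 5 * sum(depths)))
    overh <- max(sample(seq.int(5L, config$readLength - 5L),
                        min(nreads, 50L), replace = TRUE))
    known <- if (five) "acceptor" else "donor"
    jx[[length(jx) + 1L]] <- data.frame(
      chrom = locus$chrom, start = jstart, end = jend,
      strand = locus$strand, read_count = nreads, max_overhang = overh,
      anchor_status = "partially_novel", known_side = known,
      stringsAsFactors = FALSE)
  }
  list(tracks = tracks,
       junctions = do.call(rbind, jx),
       depths = data.frame(cell_id = cell_ids,
                           total_mapped_reads = vapply(tracks,
                             totalMappedReads, numeric(1)),
                           depth = depths, mode = modes,
                           stringsAsFactors = FALSE),
       truth = data.frame(cell_id = cell_ids, mode = modes,
                          stringsAsFactors = FALSE))
}

#' Simulate an enhancer cohort with bidirectional eRNA signal
#'
#' Active enhancers receive symmetric coverage bumps centered `bumpOffset`
#' bp either side of the enhancer center (Gaussian, SD `bumpSd`), on top of
#' a uniform background shared with inactive enhancers; per-base counts are
#' Poisson and per-cell depths log-normal.
#'
#' @param nActive,nInactive enhancer counts (defaults 20 and 20).
#' @param nCells number of cells (default 30).
#' @param flank half-window simulated around each center, bp (default 1000).
#' @param background per-base background rate for a depth-1 cell.
#' @param bumpHeight peak per-base rate of each bump.
#' @param bumpOffset,bumpSd bump center distance and SD, bp.
#' @param depthMeanLog,depthSdLog per-cell depth spread.
#' @param totalReadsBase mapped-read total of a depth-1 cell.
#' @param readLength read length for window read-count estimates.
#' @param seed integer seed.
#' @return list with `enhancers` (`GRanges` with `center` metadata, truth
#'   label in `active`), `tracks` (raw per-cell [CoverageTrack-class] over
#'   all windows), `windowCounts` (enhancer x cell matrix of estimated read
#'   counts in the center +/- 400 bp window), `totals` (per-cell mapped-read
#'   totals) and `truth`.
#' @export
simulateEnhancerCohort <- function(nActive = 20L, nInactive = 20L,
                                   nCells = 30L, flank = 1000L,
                                   background = 0.02, bumpHeight = 0.5,
                                   bumpOffset = 300L, bumpSd = 60,
                                   depthMeanLog = 0, depthSdLog = 0.5,
                                   totalReadsBase = 4e6, readLength = 76L,
                                   seed) {
  if (missing(seed)) stop("simulateEnhancerCohort requires a seed")
  nE <- nActive + nInactive
  gap <- 10L * flank
  centers <- gap * seq_len(nE)
  enh <- GenomicRanges::GRanges("chrE",
    IRanges::IRanges(centers - 100L, centers + 99L))
  names(enh) <- sprintf("enh%03d", seq_len(nE))
  S4Vectors::mcols(enh)$center <- centers
  active <- c(rep(TRUE, nActive), rep(FALSE, nInactive))
  S4Vectors::mcols(enh)$active <- active
  rel <- seq.int(-flank, flank - 1L) + 0.5
  bump <- stats::dnorm(rel, -bumpOffset, bumpSd) +
          stats::dnorm(rel, bumpOffset, bumpSd)
  bump <- bump / max(bump)
  rate_active <- background + bumpHeight * bump
  rate_inactive <- rep(background, 2L * flank)
  windows <- GenomicRanges::GRanges("chrE",
    IRanges::IRanges(centers - flank, centers + flank - 1L))
  set.seed(seed)
  depth <- stats::rlnorm(nCells, depthMeanLog, depthSdLog)
  cell_ids <- sprintf("cellE%03d", seq_len(nCells))
  tracks <- vector("list", nCells)
  counts <- matrix(0, nrow = nE, ncol = nCells,
                   dimnames = list(names(enh), cell_ids))
  win_idx <- seq.int(flank - 400L + 1L, flank + 400L + 1L)  # center +/- 400
  for (c_ in seq_len(nCells)) {
    vals <- vector("list", nE)
    for (e_ in seq_len(nE)) {
      lam <- (if (active[e_]) rate_active else rate_inactive) * depth[c_]
      v <- stats::rpois(2L * flank, lam)
      vals[[e_]] <- v
      counts[e_, c_] <- round(sum(v[win_idx]) / readLength)
    }
    tracks[[c_]] <- CoverageTrack(cell_ids[c_], windows, vals,
      max(1, round(totalReadsBase * depth[c_])))
  }
  names(tracks) <- cell_ids
  list(enhancers = enh, tracks = tracks, windowCounts = counts,
       totals = vapply(tracks, totalMappedReads, numeric(1)),
       truth = data.frame(enhancer = names(enh), active = active,
                          stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' Emits the genome FASTA, annotation GTF, one bedGraph per cell, and the
#' junction, depth and truth TSVs. All writers are byte-deterministic, so
#' rerunning a simulation with the same seed reproduces every file exactly.
#' Analysis functions never read the truth table.
#'
#' @param locus a [locusSpec()].
#' @param sim result of [simulateCells()].
#' @param genomeSim result of [simulateGenome()] (or `NULL` to skip
#'   FASTA/GTF).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(locus, sim, genomeSim = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(genomeSim)) {
    Biostrings::writeXStringSet(genomeSim$genome,
                                file.path(dir, "genome.fa"))
    writeGtf(genomeSim$transcripts, file.path(dir, "annotation.gtf"))
    utils::write.table(genomeSim$truth, file.path(dir, "truth_locus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (tr in sim$tracks)
    writeBedGraph(tr, file.path(dir, paste0(cellId(tr), ".bedGraph")))
  writeJunctions(sim$junctions, file.path(dir, "junctions.tsv"))
  utils::write.table(sim$depths[c("cell_id", "total_mapped_reads")],
                     file.path(dir, "depths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
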