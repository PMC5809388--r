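---
title: "Detecting recursive splicing from single-cell total RNA-seq coverage"
author: "recsaw authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recursive splicing from single-cell total RNA-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recsaw)
library(GenomicRanges)
```

## The problem

Recursive splicing (RS) removes very long introns in several steps: a cryptic
splice site inside the intron acts first as a 3' acceptor for the upstream
intron segment and then reconstitutes a 5' donor for the downstream segment.
Full-length total RNA-seq captures nascent transcripts, so intronic read
coverage carries a footprint of this process. Under co-transcriptional
splicing, a position `x` inside an intron remains part of the nascent RNA
from the moment the polymerase passes it until the segment containing it is
excised; its expected coverage is therefore proportional to the distance from
`x` to the end of its segment. A normally spliced intron shows one linear
decay from the intron 5' end to its 3' end; a recursively spliced intron
shows a **sawtooth**: the same decay, resetting upward to the segment-start
level at every RS site.

`recsaw` implements the full analysis chain around this signature for
single-cell (or bulk) coverage data: candidate RS-site selection from splice
junctions, sawtooth detection by nested linear regression, subsampling-based
sensitivity modelling with per-cell RS calls, the accompanying coverage and
enhancer-RNA detection metrics, and a seeded simulator that generates
coverage with exactly the statistical structure the analyses assume.

## Candidate selection

Candidates come from splice-junction tables (7–8 column TSV; see
`readJunctions()`), not from coverage. A junction becomes an `RSCandidate`
only if all of the following hold, each a strict inequality:

* it lies in an intron longer than 150 kb that no other gene's exon touches
  (`selectLongIntrons()`);
* it is *partially novel*: exactly one boundary coincides with an annotated
  splicing boundary, and that boundary is the host intron's own edge;
* the intronic (novel) anchor carries the appropriate splice motif — one of
  the 16 pentamers that account for at least 1% of annotated 5' splice sites
  when the novel side is a donor, or a −22..−1 window with more than 11
  pyrimidines ending in YAG when the novel side is an acceptor
  (`has5ssMotif()`, `has3ssMotif()`);
* its split alignments have more than 10 nt of overhang;
* it spans more than 5 kb, and the RS position is more than 5 kb from both
  intron boundaries.

Ambiguity characters (N) fail motif matching — conservative calling.
`rs_position` is expressed in transcription-direction bp from the intron 5'
end, which makes everything downstream strand-agnostic; the strand symmetry
is asserted by tests on mirrored loci.

## The sawtooth test

Per-cell coverage is depth-normalized to counts per million
(`normalizeByDepth()`; the 10^6 scale is cosmetic — it cancels in every
regression and test) and summed across cells (`sumTracks()`). The pooled
intronic coverage is partitioned into 5-kb bins from the intron 5' end
(terminal partial bins are dropped so every bin has equal exposure), and two
nested ordinary-least-squares models are fitted to the per-bin sums:

* baseline: `y = b0 + b1 * x`
* augmented: `y = b0 + b1 * x + b2 * D`

where `x` is the bin midpoint and `D` is 1 for bins between the upstream
exon and the RS position (assigned by bin midpoint), 0 after it. The
improvement is scored by the F statistic
`F = (RSS_base − RSS_aug) / (RSS_aug / df_aug)` on (1, df_aug) degrees of
freedom, with detection requiring `p < 1e-5` (configurable `alpha`).

Because the F-test only measures *any* step, four configurable shape
criteria (`shapeConfig()`) confirm an actual sawtooth:

* the augmented slope is negative (nascent coverage decays 5'→3');
* the coverage **reset at the RS site is positive**. With `D = 1` upstream,
  an upward reset corresponds to a *negative* dummy coefficient, so the
  quantity thresholded is the reset height `−b2`. This is a deliberate
  design choice: a positive `b2` under this coding would describe a
  downward step at the RS site, which is the opposite of the sawtooth
  geometry (two descending ramps with an upward reset between them);
* the augmented intercept is positive;
* the augmented/baseline slope ratio lies in `[0.2, 5]` — a pure step with
  no within-segment decay drives the augmented slope to zero and fails this
  flag. There are no field-standard numeric thresholds for these four
  quantities; the defaults here are the package's own, recorded in every
  result object, and all four are configurable.

Degenerate inputs are kept distinct: fewer than 6 usable bins or all-zero
coverage yield the verdict `insufficient_data` (a 3-parameter regression
needs residual degrees of freedom); a constant dummy or constant positions
raise a rank-deficiency error.

## Detection sensitivity and per-cell calls

How many intronic reads does the test need? `estimateSensitivity()` answers
by binomial thinning: each per-base count of the pooled **raw** track is
kept with probability `f` for
`f ∈ {10^0, 10^-0.5, …, 10^-3}`, 100 replicates per fraction, and the
sawtooth test is rerun on every replicate. Thinning coverage is an
approximation to subsampling reads; it preserves the mean and, for Poisson
counts, the full distribution, which is why the simulator below uses Poisson
noise. Each replicate records an intronic read-count estimate
(`sum(coverage) / read_length`, read length 76 nt by default, a common
single-end cycle count for this application) and whether RS was
detected.

`fitDetectionCurve()` then fits a logistic model
`P(detect) = logistic(a + b * log10(reads + 1))`. The covariate scale is the
package's choice: monotone, zero-safe, and linearizing over the three
decades the fractions span. Complete separation (a perfectly sharp detection
threshold) makes the ML estimate diverge; the fit then falls back to a
weakly ridge-penalized likelihood (`lambda = 1e-3`) and flags the curve, so
downstream probability reads stay finite and monotone.

Per-cell calling (`callRsPerCell()`) is restricted to cells whose predicted
detection probability exceeds 0.95 *and* that have reads on both sides of
the RS position (`selectCells()`). Verdicts: `rs_detected` when the sawtooth
test fires; `monotonic_decrease` when the baseline slope is significantly
negative (t-test, p < 0.05) while the augmented model offers no significant
improvement — the coverage pattern of normal splicing; `indeterminate`
otherwise.

## Coverage and enhancer-RNA metrics

* `coverageProfile3p()` — the fraction `n_i / N_i` of transcripts with at
  least one covered base per distance-from-3'-end bin, among transcripts
  long enough to reach the bin. Bin edges are a parameter (log-spaced
  default): there is no canonical choice of edges.
* `exonicFractionCovered()` — a base counts as covered when at least one
  read overlaps it.
* `filterEnhancers()` / `detectFeatures()` — enhancers within 2 kb of
  annotation (boundary-gap distance) or wider than 400 bp are dropped;
  counts in the 801-bp window (center ± 400 bp) are normalized per million
  mapped reads and called detected strictly above 0.1.
* `aggregateEnhancerProfile()` — per-enhancer profiles are kept for the top
  70% by signal 75–275 bp from the center, rescaled to sum 1, binned at
  50 bp, trimmed of the top 1% of enhancers per bin, then averaged. The
  output is a convex combination of profiles, so the bin means sum to at
  most 1.
* `histoneErnaFilter()` — eRNA definition by promoter chromatin:
  `log2(H3K4me1 / H3K4me3) > 0.58` on normalized TSS ± 500 bp counts, with a
  0.5-normalized-unit pseudocount added to both marks when either is zero
  (flagged per feature).
* `classifyNonpolyA()` — loose calls need FDR < 0.05, depletion in the
  poly(A) library and a total-RNA fitted mean of at least 10; strict calls
  additionally need a poly(A) fitted mean below 1; fully intronic assemblies
  (class code "i") are never classified. Strict ⊆ loose by construction.
  The differential fit itself is an input: it is an off-the-shelf
  negative-binomial analysis, not part of this package's contribution.
* `compareRegionCoverage()` — two-region isoform comparison: per-cell means
  normalized to the all-cell average per region, paired Wilcoxon signed-rank
  per cell group with Bonferroni correction across groups. Ties are dropped;
  the exact null is used for n ≤ 25 pairs, the corrected normal
  approximation above. Note that because each region is normalized by its
  own all-cell mean, a strong perturbation in one group necessarily shifts
  the relative level of the remaining groups; the test is informative when
  the perturbation is confined to a minority of cells.

## The simulator and what it does (not) emulate

`locusSpec()` + `simulateCells()` generate a two-exon gene with one long
intron (default 300 kb, the size regime where recursive splicing is
observed) under three modes: `recursive` (sawtooth, default one five-prime
RS site at the midpoint), `normal` (monotone decay) and `unexpressed`.
Defaults, chosen once on realism grounds:

* linear intron decay from 1 to a floor of 0.25 of the ramp-start level —
  linear because the residence-time argument above is linear in distance,
  with a nonzero floor for post-transcriptional intronic background;
* exon plateau at 3× the ramp start (exonic coverage exceeds nascent
  intronic coverage);
* per-base counts are Poisson around the scaled shape — the natural count
  noise model, and exactly closed under the binomial thinning used by the
  sensitivity stage;
* per-cell depth is log-normal (`meanlog = log 0.03`, `sdlog = 1` at the
  ramp start): a right-skewed depth spread typical of single-cell libraries,
  placing a median cell's intronic read count near the detection threshold
  so that cell-selection logic is actually exercised;
* junction records carry the truth anchors with overhangs drawn uniformly
  in [5, read length − 5] nt.

`simulateGenome()` writes random background sequence with exact motif
windows planted at RS sites, so every simulated candidate re-validates
against its own genome. `simulateEnhancerCohort()` generates bidirectional
coverage bumps 300 bp either side of active enhancer centers (SD 60 bp) over
a uniform background, matching the bimodal aggregation profile expected of
enhancer RNA.

Deliberately *not* emulated: amplification and positional bias, PCR
duplicates, strand-specific artifacts, mappability, multi-isoform hosts,
overlapping transcription, and read-level placement (coverage is simulated
directly; junctions are emitted as records). Passing tests on these
simulations therefore demonstrate the statistical machinery under the
model's own assumptions — they do not certify performance on real libraries,
where the linear-decay assumption is only an approximation.

## Numerical choices and verification scale

* All candidate thresholds are strict inequalities.
* OLS is solved by `stats::lm` (QR); tests require agreement with an
  explicit normal-equation oracle to 1e-8 relative error on fixtures up to
  50 bins.
* `F` conventions at the boundary: identical fits give `F = 0, p = 1`; a
  perfect augmented fit with imperfect baseline gives `p = 0`; an augmented
  RSS above the baseline RSS (impossible for nested OLS beyond numerical
  tolerance 1e-9 relative) is an error.
* Null calibration is verified on 2 000 seeded normal-splicing simulations
  of the standard locus at pooled depth 5 (the pooled equivalent of the
  100-cell default cohort): the F-test p-values are checked against
  Uniform(0,1) by a Kolmogorov–Smirnov test, and false detections at
  `alpha = 1e-5` are counted. Binned sums of thousands of Poisson counts are
  close to Gaussian, and the mild variance gradient along the decay (4:1
  between intron ends at floor 0.25) does not measurably distort the test —
  this was checked across depths 0.3–3 and floors 0.1–0.5 during design.
* Power is verified at the standard geometry (60 bins, reset ≈ 60 Poisson
  SDs) and at a shorter 20-bin geometry with a reset ≈ 20 per-bin SDs. Two
  effects keep the small-step, few-bin regime out of reach of 95% power
  under the full verdict: the dummy is strongly collinear with position
  (r ≈ −0.87 for a midpoint site), which inflates the F-test's standard
  error about four-fold, and the slope-ratio shape flag depends on the
  noisy baseline-slope estimate, which at 20 bins and shallow depth drifts
  outside its default [0.2, 5] band in a nontrivial fraction of seeds. A
  reset of only ~3 per-bin SDs with 20 bins therefore does *not* reach 95%
  detection; the verified regimes are the ones the default simulations
  actually produce.
* Problem sizes in the test suite (2 000 null replicates, 100 power seeds,
  1 000 specificity seeds, 100-cell cohorts, 100 subsampling replicates per
  fraction) were chosen to estimate every rate to ~1–3% standard error.
* Determinism: every stochastic entry point takes an explicit seed;
  file writers are byte-deterministic, and reruns under one seed are
  asserted byte-identical, including through the command-line driver.

## Limitations

The linear model is deliberately simple; it underfits curved decay profiles
and multi-rate elongation, and single-cell verdicts near the eligibility
boundary are noisy — cells with weak sawtooths are reported
`indeterminate` rather than forced into either class. Junction anchor
classification reproduces the *definition* of partially novel junctions, not
any specific upstream tool byte-for-byte. Coordinate convention: in memory
everything is GRanges (1-based inclusive); on disk, bedGraph/BED/junction
and candidate TSVs are 0-based half-open.
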