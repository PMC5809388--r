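# recsaw

Detection of **recursive splicing (RS)** from per-cell genome coverage
produced by full-length total RNA sequencing, together with the coverage and
enhancer-RNA detection metrics that accompany this kind of data, and a
seeded simulator that provides ground truth for every stage.

## The science in brief

Very long introns (> 150 kb) are often removed in several steps: a cryptic
intronic splice site first serves as a 3' acceptor for the upstream segment
and then reconstitutes a 5' donor for the rest. Because total RNA-seq
captures nascent transcripts, intronic coverage encodes this process. A
position `x` stays in the nascent RNA until its segment is excised, so its
expected coverage is proportional to the distance from `x` to the segment
end: a normal intron decays linearly 5'→3', while a recursively spliced
intron shows a *sawtooth* — the decay resets upward at each RS site.

`recsaw` tests the sawtooth with two nested OLS models on pooled,
depth-normalized coverage summed in 5-kb bins along the intron:

    baseline:   y = b0 + b1·x
    augmented:  y = b0 + b1·x + b2·D,   D = 1 upstream of the RS site

scored by `F = (RSS_base − RSS_aug) / (RSS_aug / df_aug)` with detection at
`p < 1e-5`, plus four configurable shape criteria (negative slope, positive
coverage reset `−b2`, positive intercept, augmented/baseline slope ratio in
[0.2, 5]). Candidate RS sites come from splice-junction tables filtered on
intron length (> 150 kb), partial anchor novelty, intronic splice motifs
(a 16-pentamer 5'-site whitelist, or a > 11-pyrimidine −22..−1 window ending
in YAG), > 10-nt overhangs and > 5-kb spans. Detection sensitivity as a
function of intronic read depth is estimated by binomial thinning of the
pooled coverage (100 replicates at fractions 10^0 … 10^-3) followed by a
logistic fit on `log10(reads + 1)`, which gates per-cell RS calls at
detection probability > 0.95.

## Worked example

Simulate a 100-cell cohort over a 300-kb intron with an RS site at the
midpoint, find the candidate from the junction table, and test the sawtooth:

```r
library(recsaw)

locus <- locusSpec("recursive")                 # 300-kb intron, RS at midpoint
gen   <- simulateGenome(locus, seed = 11)
sim   <- simulateCells(locus, simConfig(nCells = 20, seed = 12))

cand <- findRsCandidates(sim$junctions, gen$transcripts, gen$genome)
cand[, c("gene_id", "rs_position", "side", "known_side", "motif")]
#>   gene_id rs_position       side known_side motif
#> 1   geneS      150000 five_prime   acceptor GTAAG

pooled <- sumTracks(lapply(sim$tracks, normalizeByDepth))
res <- detectRs(pooled, cand[1, ])
res$verdict        # "rs_detected"
res$p_value        # 1.47e-38
res$f_stat         # 1063.5
-res$augmented$beta2  # 274.6: the fitted coverage reset at the RS site
```

The verdict says the augmented model improves the fit far beyond chance
(`p` well under the 1e-5 threshold) and all four shape flags hold; the
positive reset height is the sawtooth jump in summed-CPM units per 5-kb
bin. Running the same cohort under `locusSpec("normal")` gives
`not_detected`, and per-cell calls on eligible cells
(`selectCells()` + `callRsPerCell()`) separate `rs_detected` cells from
`monotonic_decrease` (normally splicing) cells.

A thin command-line driver over the same functions is installed at
`inst/scripts/recsaw.R` with `simulate`, `candidates`, `detect` and
`sensitivity` subcommands.

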