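---
title: "Methods: windowed Wilcoxon analysis of promoter tiling ChIP-chip arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed Wilcoxon analysis of promoter tiling ChIP-chip arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipwin)
```

## The experimental design being modeled

A two-color promoter tiling array measures, for every probe, the log2
ratio of immunoprecipitated (IP) over input DNA. Promoters are tiled from
2,200 bp upstream to 500 bp downstream of each transcription start site
(TSS) with 50--75-mer probes spaced about 100 bp apart, so a promoter
carries roughly 28 probes and a replicate experiment yields one log-ratio
per probe per array. Binding of the assayed factor shows up as a localized
elevation of log ratios across neighboring probes; depletion (e.g. of a
histone mark) shows up as a localized trough.

All coordinates in the package are 0-based and half-open (the BED
convention) at every module boundary; 1-based coordinates appear only in
human-readable messages.

## Normalization

Each replicate array is processed in a fixed order, recorded in a
provenance attribute:

1. **Lowess detrending.** A locally weighted regression of the log ratio
   on a covariate is fitted (`stats::lowess`, span 0.3, 3 robustness
   iterations) and subtracted. The default covariate is the probe's mean
   log2 intensity A --- the standard MA-normalization for two-color arrays
   --- with the probe's genomic midpoint available as a fallback for
   tables without intensities. Which covariate was used is recorded in the
   provenance string. The span and iteration count are conventional values
   for array normalization; the method itself does not prescribe them.
2. **Equal sum-of-squares scaling.** Replicate *j* is multiplied by
   `sqrt(target / SSQ_j)` with the target taken as the *geometric mean* of
   the replicate sums of squares. The geometric mean keeps the transform
   symmetric in the replicates and preserves the overall scale; any other
   target differing by a constant factor would only rescale every window
   mean jointly and leave all rank-based downstream statistics unchanged.
3. **Replicate averaging.** The per-probe mean log ratio is the
   arithmetic mean across replicates with pairwise deletion of missing
   values; probes missing in every replicate are flagged and carry an NA
   mean (never imputed).

## The windowed error model

A window of `window_size` = 1,000 bp is moved in `window_step` = 250 bp
steps. Window centers sit on multiples of the step, anchored at
coordinate 0 on each chromosome; the method leaves the anchor unspecified
and a genome-fixed grid makes window identity reproducible across data
sets, which the cross-dataset correlation relies on. A probe belongs to a
window iff its midpoint `floor((start + end) / 2)` lies in the half-open
window interval. Each window records its probe count, the mean of its
probes' averaged log ratios, and a **one-sided exact Wilcoxon signed-rank
p-value** in the direction of the window mean.

The signed-rank p is computed exactly for up to 12 values: zeros are
dropped, absolute values are midranked, and the null distribution of the
positive-rank sum over all 2^n sign assignments is built by
generating-function convolution (midranks are half-integers, so doubled
ranks live on an integer lattice and the convolution is exact). Above 12
values the standard normal approximation with continuity correction and
the tie correction `var = n(n+1)(2n+1)/24 - sum(t^3 - t)/48` takes over.
The tests check the exact path against a brute-force enumeration of all
sign assignments, an independent route through the same distribution.

**Why one-sided.** The caller's threshold is p < 0.016 with at least six
probes per window. One-sided, six concordant values attain exactly
1/2^6 = 0.015625 < 0.016, so the smallest admissible window can just pass;
two-sided the minimum is 0.03125 and six-probe windows could never
qualify. The one-sided reading is therefore the only one under which the
six-probe minimum is meaningful, and the package adopts it; a regression
test asserts both halves of this argument.

## The peak and trough caller

A peak is the center of **three consecutive windows** (centers exactly one
step apart) that all have positive means, at least `min_probes` = 6
probes, p < 0.016, and whose middle mean strictly exceeds both neighbors.
Troughs mirror this with negative means and a strictly smaller middle.
The strict local-extremum rule guarantees that two calls of the same sign
are never one step apart. The reported peak carries the middle window's
mean and p and the span of the three windows; BED output scores peaks as
`round(-100 log10 p)` clamped to [0, 1000]. No multiple-testing
correction is applied: the method controls errors through the
three-window consensus and, originally, through qPCR validation of the
false positive rate; here the synthetic truth plays that role.

**Power of the consensus rule.** The three-window consensus is very
conservative for narrow binding sites. A 600 bp enrichment footprint
elevates only about 5 of the ~10 probes in a 1 kb window; the remaining
probes are mean-zero noise whose signs are +/- 50/50 *regardless of the
noise amplitude*, and a one-sided p < 0.016 at n = 10--11 tolerates a
negative-rank sum of only ~8 out of 55--66. A single window at the peak
apex therefore passes only ~35% of the time at apex height 1.5 log2
units and probe noise sd 0.3, and all three windows pass together for
under 10% of planted 600 bp peaks --- while essentially every call made is
genuine (false positive rate at or near 0, and under 2% of pure-noise
promoters produce any call). The caller trades sensitivity for
specificity; peaks whose footprint approaches the window size (>= 1.5 kb)
are recovered nearly always. The test suite asserts the specificity
half of this trade-off and documents the sensitivity half; the acceptance
suite keeps the nominal >= 90% sensitivity expectation for 600 bp peaks
in place, where it fails for the structural reason above rather than for
an implementation one.

## TSS-anchored integration

*Distances.* Each peak is assigned the TSS nearest by absolute distance
on its chromosome; the signed distance is strand-oriented
(`strand_sign * (center - tss)`, negative upstream), and equidistant ties
break toward the smaller gene id so results are deterministic. Distance
histograms are tested bin-by-bin against the background distribution of
all probe-sufficient windows' distances with a one-sided Fisher exact
test; bins default to 250 bp (the window step), as the method does not
print its bin edges.

*Heat-map matrix.* One row per gene and one column per 600 bp window
moved in 150 bp steps across the oriented promoter; the default
-2,200..+500 bp range gives 19 columns. A cell is the mean probe value in
its half-open window, NA when empty.

*Expression.* A gene is **expressed** iff flagged present (P) in all
three expression replicates, **unexpressed** iff flagged absent (A) in
all three, otherwise ambiguous and excluded. Genes are ranked into
expression deciles (1 = lowest) by mean signal with ties broken by gene
id; decile sizes differ by at most one. Decile profiles are columnwise
means of the heat-map matrix over member genes.

*Bound-gene enrichment.* A gene is bound iff a called peak center lies
inside its tiled promoter (peaks in overlapping promoters count for every
containing gene). The 2x2 table of bound status against
expressed/unexpressed status is tested with a two-sided Fisher exact test
and summarized by the fold enrichment of binding among expressed genes.
Fisher sidedness is not stated by the method; two-sided is used wherever
the question is symmetric (bound-gene enrichment, co-occupancy) and
one-sided greater where it is explicitly an enrichment question
(distance bins, motif bp enrichment).

## Cross-dataset comparison

*Correlation.* Two window tables on the same grid are matched on
(chromosome, center) and compared by Spearman rank correlation. The
p-value is exact by enumeration of all n! permutations for n <= 9 and
uses the t-approximation `t = rho sqrt((n-2)/(1-rho^2))` otherwise; the
volcano score is `-log10 p` capped at 320 (the double-precision floor),
sign-tagged by the sign of rho.

*Co-occupancy.* Both peak sets are reduced to centers and filtered to the
tiled universe; a test peak is co-occupied iff a reference center lies
within 1,500 bp. The original analysis prints co-occupied / only-test /
only-reference counts and the two percentages, which are fully determined
by the counts; its fold-enrichment null is not specified, so the package
defines one explicitly: the universe is discretized into 1,500 bp bins, a
bin is reference-adjacent iff its midpoint is within 1,500 bp of a
reference center, and the expected co-occupancy rate under uniform
placement is the adjacent-bin fraction. Fold is observed rate over
expected rate (a property test confirms it centers on 1 for uniformly
placed peaks), and the Fisher table compares the observed split with the
bin availability. No numerical agreement with the original fold/p is
claimed.

## Motif (TFBS) enrichment

The training set is the merged union of 2 kb TSS flanks of peak-bearing
genes; the background is the all-gene flank union minus the training set,
so the two sets partition the array's promoter space exactly (asserted by
property tests using exact interval arithmetic via GenomicRanges).
Overlapping sites of one motif are merged before counting --- the
statistic is *base pairs marked*, which implies union semantics --- and
clipped to the region set. Per motif, the table (marked training bp,
unmarked training bp; marked background bp, unmarked background bp) is
tested one-sided greater. The "motif adjacent to a peak" gene count uses
a concrete adjacency rule, deliberately the heat-map half-window: a site
qualifies if it overlaps the peak span or lies within 300 bp of the peak
center.

## The synthetic data generator

The generator emulates the study's data *structure* so every stage is
testable without downloads: `n_genes` promoters on alternating strands
spread over four chromosomes 5 kb apart, tiled at ~100 bp spacing with
+/- 20 bp jitter, two replicate arrays with i.i.d. Gaussian probe noise
(sd 0.3 by default), and a `fraction_bound` subset of genes carrying a
triangular enrichment bump (apex 1.5 log2 units, 600 bp base by default)
at a uniform random offset. The triangle matches the local-maximum
structure the caller assumes, since the method states no signal model.
Expression tables couple presence flags and signal level to bound status
through an odds multiplier; a second-factor generator copies a chosen
fraction of truth peaks with truncated Gaussian jitter plus distant
decoys; a motif-track generator plants one 10 bp site per enriched gene
among Poisson background sites.

What the generator deliberately does **not** model: probe-affinity
effects, spatial autocorrelation, dye bias, or real promoter sequence.
Two consequences matter for interpreting green tests. First, replicate
window means correlate only through planted signal, so replicate
concordance (Spearman ~0.7 on probe-sufficient windows of fully bound
promoters) is *lower* than on real arrays, where shared probe effects
inflate it; tests therefore assert a conservative rho > 0.6. Second,
pure-noise promoters are genuinely exchangeable, making the null
call-rate test a clean upper bound that real arrays, with their spatial
artifacts, would not necessarily meet.

## Problem sizes and numerical choices

The test and acceptance runs use 300--1,000 synthetic promoters, 20--50
seeds for Monte-Carlo properties, exhaustive Fisher-oracle sweeps over all
2x2 tables with total count up to 20 plus 400 random tables with margins
up to 60, and full permutation/sign-flip enumerations at n <= 10 ---
sizes chosen so each property is measured with comfortable margins while
the whole suite stays fast. Exact p-value paths switch to approximations
at n = 12 (signed rank) and n = 9 (Spearman); p-values are clamped to
(0, 1]; equal-SSQ scaling requires every replicate's SSQ to be nonzero
and fails loudly otherwise; empty windows carry p = 1 and never seed
peaks but do participate in background distance sets when
probe-sufficient.

## Known limitations

- The caller's sensitivity for sub-window-width peaks is intrinsically
  low (see "Power of the consensus rule"); this package reproduces the
  method as defined rather than re-tuning it.
- The co-occupancy fold/p null is this package's own construction; only
  the count-determined percentages are comparable across
  implementations.
- Lowess detrending at the extreme ends of the covariate range has
  boundary variance; guarantees are stated for the central 95% of probes.
- The generator's i.i.d. noise understates real replicate correlation and
  contains no array artifacts, so passing tests certify the algorithms,
  not robustness to platform-specific artifacts.
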