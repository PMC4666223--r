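---
title: "Region-level methylation analysis with dmrrank: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level methylation analysis with dmrrank: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrrank)
```

This vignette documents the statistical model behind `dmrrank`, the
defaults and why they were chosen, what the synthetic-data generator does
and does not emulate, and the known limitations. It is the package's
account of its own design; every number shown here is computed by the code
in this document or by the test suite.

## The testing model

### Per-probe directional rank tests

For each probe and each unordered pair of sample groups, `dmrrank`
computes **two one-sided two-sample Mann–Whitney U tests**: one p-value
for higher methylation in each group. Keeping both directions (rather than
a single two-sided p) matters because region-level combination is done per
direction: a region is only called when its probes agree on *which* group
is higher, and the reported direction is the one with the smaller
combined q.

Rank tests need no normality assumption and are invariant under monotone
transforms, so the choice of testing beta values rather than M-values
(logit2 betas) has no effect on p-values; betas are used directly, and
the beta scale is kept for effect sizes because "a 0.25 change in
methylation rate" is the quantity analysts filter on.

Exact-vs-approximate switching is an implementation choice the method
itself does not dictate. Our contract: the **exact** null distribution of
U (via `stats::pwilcox`) whenever the pooled sample has no ties and at
most 16 observations; otherwise the normal approximation with
tie-corrected variance and a 0.5 continuity correction. With all pooled
values identical, both one-sided p-values are defined as 1 (no evidence in
either direction). P-values are clamped away from 0 so the downstream
z-transform stays finite.

```{r mwu}
# complete separation at n=3 vs 3: the most extreme of the C(6,3)=20 labelings
mwu_one_sided(c(4, 5, 6), c(1, 2, 3), "a_greater")$p
```

### Spatial correlation of probe z-scores

Neighbouring CpG probes are correlated; combining their p-values as if
independent would overstate the region-level evidence. `dmrrank` estimates
the correlation of probe z-scores (`z = qnorm(1 - p)`) as a function of
genomic distance, in bins with default upper edges 1, 51, 101, 201, 501
and 1001 bp — a short ladder that resolves the sub-kilobase scale where
array probes cluster, while pairs beyond 1 kb are treated as independent.
The estimate is genome-wide (not per chromosome): z-score autocorrelation
is a property of probe spacing and shared biology, not of a particular
chromosome, and pooling gives far more pairs per bin. Bins with fewer
than 30 pairs, or zero variance, fall back to 0, and **negative estimates
are truncated at 0**: correlation can only make the combination more
conservative, never manufacture extra effective tests. The ACF is
estimated separately for each group pair and each direction, from the same
z-scores being combined.

### Stouffer–Liptak combination

For a region with member p-values \(p_1,\dots,p_k\) and correlation matrix
\(\Sigma\) (unit diagonal, off-diagonals looked up from the binned ACF at
the pairwise probe distances),

\[ C = \frac{\sum_i z_i}{\sqrt{\sum_{ij} \sigma_{ij}}},\qquad
   p_{\text{region}} = 1 - \Phi(C), \qquad z_i = \Phi^{-1}(1-p_i). \]

A singleton region is an identity; independence gives the classic
Stouffer combination; complete dependence collapses to a single test. If
the denominator sum is not positive the independence denominator \(k\) is
used. Inputs are clamped to \([10^{-16}, 1-10^{-16}]\) before the
z-transform.

```{r sl}
stouffer_liptak(rep(0.05, 4), diag(4))   # independent: 1 - pnorm(2*qnorm(.95))
stouffer_liptak(rep(0.05, 4), matrix(1, 4, 4))  # fully dependent: one test
```

### Sidak correction and the effective test count

Region p-values are corrected with a one-step Sidak adjustment,
\(q = 1-(1-p)^m\), computed via `expm1`/`log1p` so tiny p-values survive.
The effective count is **span-based**: `m = floor(total tested span /
region span)` — how many regions of this size fit into the total bases
under test (the width of the union of all regions that contain at least
one probe). This matches the logic of correcting over "all possible
regions of that size"; a region-count-based alternative
(`sidak_method = "count"`) is exposed for users who prefer correcting
over the literal number of tested regions. For disjoint equal-width
tilings the two coincide.

### Change summaries, filtering, orientation

Per probe, the change is the difference of group-median betas; a region
reports the min, median and max across its probes. Group pairs are
oriented lexicographically and change is always `group2 - group1`, so
signs are reproducible; both directional p- and q-values are always
reported, so no information is lost to the convention. Regions pass when
`min(q_A, q_B) <= q_cutoff` *and* `|change_median| >=
min_abs_median_change`; results are sorted by q with (chrom, start) as
the tie-break.

## Region generation

Tilings are half-open windows `[0,w), [w,2w), ...` per chromosome with the
partial final window kept, so every window size exactly partitions the
genome. Promoters are one `span_bp` window per gene anchored at the TSS,
strand-aware; the default orientation is **downstream** (into the gene
body, TSS included), with `orientation = "upstream"` (TSS excluded)
available — annotation conventions differ on which side "promoter" means,
so both are provided rather than asserting one. Exon extraction collapses
intervals duplicated across transcripts. Coordinates are 0-based half-open
everywhere, probes are points, and a probe belongs to `[s, e)` iff
`s <= pos < e`.

## Quality control and normalization

The detection-p filter is two-step: first drop samples whose failed-probe
fraction (detection p above `probe_p_cutoff`, default 0.01) exceeds
`sample_fail_fraction` (default 0.1) — conventional 450k QC values — then
drop any probe failing in **any** surviving sample. The any-sample probe
rule (rather than a per-probe failure fraction) is this package's
contract: downstream rank tests need complete columns, and imputation is
out of scope, so a probe that failed anywhere is removed. For the same
reason missing beta values are rejected at load time rather than silently
handled.

The optional `quantile_normalize()` is a plain cross-sample quantile
normalization (each sample's sorted vector replaced by the mean of sorted
vectors, ties interpolated); array-chemistry-aware normalization belongs
upstream of this package.

## Enrichment analysis

Gene-linked regions are reduced to one score per gene: the region with the
smallest q wins (ties: larger `|change_median|`, then name), and the score
is `sign(change_median) * -log10(q)` — significance sets the magnitude,
the direction of methylation change sets the sign. A `metric = "change"`
alternative ranks by the raw median change instead, for users who care
about effect size over significance.

The enrichment score is the classic weighted running sum: hits add
`|score|^p / sum_hits |score|^p` (default `weight_p = 1`; 0 gives the
unweighted Kolmogorov–Smirnov form), misses subtract `1/(N - N_hit)`; ES
is the signed maximum deviation. Significance uses **gene permutation**
(random same-size gene subsets, seeded): phenotype permutation would
require re-running the entire region pipeline per shuffle, which is
disproportionate for a pre-ranked list; the trade-off (gene permutation
ignores inter-gene correlation) is the standard one for pre-ranked GSEA.
`p = (1 + #{|ES_null| >= |ES_obs|})/(n_perm + 1)` with `n_perm = 1000` by
default, so the smallest attainable p is `1/1001`. No normalized ES or
cross-set FDR is computed by default; Benjamini–Hochberg across sets is
available as a flag. The leading edge is the set members at ranks up to
the peak (after it for negative ES), and the overlap heat-map input is the
Jaccard matrix of leading edges across sets with `p_perm <= 0.05`.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the statistics rely on:

* probe positions from exponential spacings (default mean 500 bp, 2000
  probes on 2 chromosomes — a desk-scale stand-in for array probe
  clustering);
* a bimodal baseline per probe (60% low mode Beta(2,10), else Beta(10,2)),
  matching the characteristic two-peak beta distribution of arrays;
* a probe-level random effect shared by all samples with exponential
  spatial decay (default sd 0.04, correlation length 300 bp), giving
  z-score autocorrelation for `estimate_acf()` to find;
* spiked regions: grid-aligned windows (so they coincide with tiles of the
  same width) where one group's betas shift by `delta`; spiked probes draw
  their baseline from an intermediate Beta(4,6) mode so a +0.25 shift
  stays representable in [0, 1] — without this, truncation at 1 would
  attenuate the programmed effect;
* i.i.d. Gaussian noise (default sd 0.05, a typical technical replicate
  spread) and truncation to [0, 1];
* detection p-values near 0 with a configurable failure rate.

Default group sizes are 8 vs 8 — small enough for the exact rank-test
path, large enough that a 0.25 delta separates groups. What the generator
does **not** emulate: Infinium type-I/II probe chemistry and dye bias,
batch effects, cell-type composition, correlated (non-exchangeable)
samples, and realistic genome-scale probe counts. Passing tests therefore
demonstrate the statistical machinery (calibration under the null,
recovery of localized shifts, correct bookkeeping), not robustness to
array artefacts — those must be handled by upstream preprocessing.

Simulation on the beta scale with truncation, rather than on the logit
scale, keeps `delta` directly interpretable as a change in methylation
rate; the cost is a small truncation bias near the boundaries, which the
intermediate-mode baseline in spiked regions keeps negligible (the
generator's self-consistency test recovers 0.25 within 0.03).

## Numerical choices and degenerate inputs

* p-values clamped to `[1e-16, 1 - 1e-16]` before any z-transform; never
  reported as 0.
* `beta_to_m()` clamps betas to `[eps, 1-eps]`, `eps = 1e-6` — bounded
  M-values without altering interior values.
* Zero-variance probes: both directional p-values are 1.
* Regions without probes are excluded from testing and counted in a
  skipped-regions report; the Sidak span covers only tested regions.
* Direction ties (`q_A == q_B`) resolve by the sign of the median change.
* Output ordering ties break by (chrom, start); gene-ranking ties break by
  `|change_median|`, then region name, then gene symbol — everything is
  deterministic.

## Problem sizes used in validation

The test suite and acceptance script run on generator defaults: 2000
probes, 2 chromosomes, 8 vs 8 samples, 10-kb tiles (about 100 regions of
roughly 20 probes each), 20 null replicates for type-I calibration, one
spike run with ten +0.25 regions, and 100-instance oracle sweeps for the
rank test and the enrichment score. These sizes give stable Monte-Carlo
estimates while keeping a full validation run in the order of a minute.

## Known limitations

* No covariate adjustment, paired designs or continuous phenotypes: the
  unit test is a two-group rank test, by design.
* No de-novo region discovery: probes are combined over *fixed* regions;
  a peak-growing approach is a different method.
* The binned-ACF covariance is an approximation; extremely irregular probe
  spacing with long-range dependence would violate it.
* Gene-permutation GSEA p-values ignore inter-gene correlation and are
  anti-conservative for sets of co-located genes — interpret the overlap
  matrix alongside them.
* The span-based Sidak `m` is an interpretive choice (documented above);
  for non-tiling region sets the count-based flag may be preferred.
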