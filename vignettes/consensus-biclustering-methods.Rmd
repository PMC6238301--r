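---
title: "Methods: consensus biclustering of promoter occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus biclustering of promoter occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promclust)
```

This vignette documents the models and procedures implemented in promclust,
the parameter choices behind them, and what the synthetic-data tests do and
do not establish about real data.

## The occupancy matrix

For each ChIP-seq experiment and each promoter, the signal is the height of
the peak whose summit lies closest to the TSS within a symmetric window
(`tss_window`, default 1000 bp). Absence of any qualifying peak is recorded
as 0 — peak-call tables enumerate peaks only, so absence must be assigned a
number, and 0 matches the "devoid of signal" reading of the heatmaps.
Distance is measured summit-to-TSS: the summit is the most informative
single point of a peak, but the measure is switchable in
`nearest_peak_height()` should interval distance be preferred. Ties
(equidistant summits) go to the larger height, then the smaller coordinate,
so the choice is deterministic.

Each experiment's heights are mapped linearly to [0, 1], after holding out
the top `winsor_fraction` (default 0.0005, i.e. 0.05 %) of values, which are
then set to 1. The held-out count is `k = floor(winsor_fraction * n)`: for
fewer than 2000 promoters `k = 0` and the winsorization is a no-op, which we
consider the conservative reading of a "top 0.05 %" rule at small n. Two
degenerate cases are fixed by convention: an all-zero experiment stays all
zero (no signal), a constant positive experiment maps to all 1 (saturated
signal), preserving the distinction between the two.

Coordinates are 0-based half-open throughout, and "overlap" always means at
least one shared base. The search window around a TSS is symmetric; strand
is deliberately ignored at this step.

## Promoter definition and activity

Two pipelines define the promoter universe:

*Annotation-based*: any TSS with another TSS within `isolation_dist`
(1000 bp, either strand, any gene) is dropped, along with its neighbors —
the whole crowded group is removed, since the 1 kb resolution of the signal
cannot separate its members. We read "within a 1 kb window" as pairwise
distance ≤ 1000 bp and compare across strands and genes; the comparison
scope is switchable. Activity is then called in the ±500 bp window around
the TSS, strand-agnostically.

*CAGE-cluster-based*: TSSs closer than 200 bp (strict) chain into clusters
by single linkage. Clusters spanning more than 1000 bp, containing both
strands, or containing TSSs of more than one annotated gene are marked
excluded with the reason rather than silently dropped; a TSS without a gene
assignment makes its cluster excluded (`multi_gene`) rather than raising an
error. Retained clusters are extended by 500 bp on each side and activity is
called strand-specifically on that region.

Activity itself uses the two CAGE peak tiers: a robust peak in the window
makes the promoter **active**; not even a permissive peak makes it
**inactive**; anything between is **low** and excluded from both sets.
Inactive promoters whose matrix column is all zeros are dropped, and within
a TSS cluster, promoters with exactly identical signal columns collapse to
the first by coordinate — very close TSSs see the same peaks and would enter
the clustering as duplicates. Inactive TSSs outside every annotated gene
span (intergenic) are also removed when a gene annotation is supplied.

## Base biclustering engines

**Sparse-SVD layers.** A bicluster is modeled as a sparse rank-1 layer
`d·u·vᵀ`. The fit alternates soft-thresholded power iterations: given the
unit vector on one side, the least-squares loading vector on the other side
is soft-thresholded, with the threshold chosen by a BIC-like criterion
`RSS/(n·p·σ̂²) + df·log(n·p)/(n·p)` evaluated on the *optimally rescaled*
thresholded vector. The rescaling matters: without it, the shrinkage the
soft threshold applies to retained loadings masks the fit improvement of
keeping a full block, and the criterion systematically over-sparsifies.
Candidate thresholds are the midpoints between consecutive sorted absolute
loadings (up to `sparsity_grid = 500` support sizes), so every sparsity
level is considered; closed forms via cumulative sums keep this O(p log p).

Robustness comes from stability selection: the fit is repeated on
`n_subsamples = 100` random subsamples of `subsample_fraction = 0.5` of the
rows and columns, and an index is retained if selected in at least
`stability_threshold = 0.6` of the subsamples that contained it (an index
absent from a subsample cannot be selected there, so the denominator is the
number of subsamples containing it). Each subsample's fit is warm-started
from the full-matrix layer's left vector restricted to the subsample:
without this, a subsample's leading direction is whichever block happens to
dominate it, and the per-layer selection frequencies are diluted roughly by
the number of blocks. The final support is additionally intersected with
the full-matrix fit. All constants are exposed as arguments.

Layers are extracted successively; after each, the rank-1 fit is subtracted
*on the layer's support only*, leaving background cells untouched. Column
(and row) sets claimed by several layers are disambiguated by assigning each
contested index to the layer with the larger mean signal, earlier layer
winning ties, so the solution's column sets always partition a subset of the
columns. Iterations stop at `tol = 1e-6` relative change or 30 iterations;
residual matrices with total sum of squares below 1e-18 are treated as zero.

**k-means + t-test.** The alternative engine partitions columns with
k-means (seeded k-means++ initialization; `stats::kmeans` provides no
k-means++ option, so the seeding is implemented here and passed as explicit
centers). For each column cluster, every row is tested with a two-sided
Welch t-test, inside vs outside; rows with p below `alpha = 0.001` form the
associated row cluster, and a row may belong to several. Clusters of fewer
than two columns get an empty row set (the test is undefined). The number of
clusters comes from an SSE elbow: the smallest k whose relative improvement
to k+1 falls below 5 %, degenerate all-equal matrices returning the smallest
candidate.

The Welch form (unequal variances) is used everywhere a "t test" is needed:
the column groups compared are routinely of very different sizes and
spreads. Degenerate inputs are mapped to finite values so that −log10(p)
bars remain drawable: two constant equal groups give p = 1, two constant
different groups give p = 1e-300 (bar height 300).

## The consensus procedure

The consensus wrapper is engine-agnostic and fully seeded: a run-seed vector
is drawn once from the master seed, the target clustering is the run with
the most column clusters (ties broken by the seeded RNG — the only place
randomness enters outside the engines), and every run is matched to the
target by maximum-overlap linear assignment on the confusion matrix. The
assignment is solved as maximum-weight bipartite matching; a lexicographic
perturbation smaller than any count difference makes the optimum unique, so
ties break deterministically toward smaller cluster indices. Surplus
clusters on the larger side stay unmapped.

Column frequencies are tallied over all runs, the target run mapping to
itself — the denominator includes the target, which we take as the literal
reading of "more than half the solutions". A column retained at
`min_freq = 0.5` therefore landed in one target cluster in more than half of
all runs; the same rule applies to rows through the row sides of the mapped
biclusters. The frequencies are stored, so re-filtering at another threshold
(`filter_consensus()`) is a pure filter — monotone by construction.

For display, columns are grouped by cluster (clusters by size, descending)
and sorted within a cluster by mean signal over the cluster's rows; rows are
grouped and sorted analogously; unassigned indices come last. Cluster
boundaries are reported for drawing separators.

## Regression feature selection

Expression is regressed on all matrix rows by OLS with intercept; the
reported statistic is the Pearson correlation between fitted and observed
values. Expression defaults to a `log1p` transform — CAGE tag counts are
heavily right-skewed and the relevant figures plot log counts — but the
transform is an argument, and the synthetic generator produces expression
*linear* in the signals, so tests and the acceptance script use the identity
transform on those inputs.

The quadruple scan is exhaustive over all `C(n, 4)` subsets (487,635 at
n = 60; confirmed by enumeration). Each subset's fit is computed from
precomputed covariance sufficient statistics — a 4×4 linear solve per
subset — which is algebraically identical to a per-subset `lm()` (tested
against it) and keeps the full 60-row scan in the tens of seconds.
Rank-deficient subsets fall back to a pseudo-inverse. "Good sets" are
subsets with r strictly greater than `fraction * r_full`
(default 0.95; "better than" is read strictly). Variable enrichment is the
upper-tail hypergeometric probability with population `C(n,4)`, successes
`C(n−1,3)`, draws `|good|`; it is exact, not an approximation, and matches
exhaustive enumeration of draws in tests.

In-sample correlation is used throughout; the scan ranks variable subsets
rather than estimating out-of-sample performance, and a nested-model
property (no quadruple beats the full model) is asserted in the tests.

## Motifs and loops

Motif hits are reduced to the smallest-p hit per (promoter, motif); ties go
to the hit closest to the TSS, then leftmost. Positions are TSS-relative and
strand-oriented. Scores enter a motifs × promoters matrix in heatmap column
order with 0 for missing hits; raw scores are used, as no normalization is
defined for them.

For loops, the promoter side is the anchor overlapping the promoter region
(the larger overlap when both anchors touch it), the other anchor is the
remote region. Among a promoter's loops, the one with the highest remote
H3K27ac is selected; the summary over the remote anchor is the **mean**
coverage (a max would be dominated by single-bin spikes; the choice is
switchable). The remote region, padded by 500 bp per side, is classified
against the enhancer segmentation with strong > weak > none precedence, and
re-centered on the position of maximum CTCF coverage (ties leftmost) ±1 kb.
Zero coverage everywhere falls back to the geometric midpoint, flagged.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* the pipeline relies on:

- `make_planted_matrix()`: disjoint blocks of elevated signal
  (`mean_signal` + Gaussian noise, clipped to [0, 1]) over a mostly-zero
  background where a cell carries a spurious peak with probability
  `background_rate` (height Uniform(0.05, 0.25)). Background sparsity is
  deliberate: real peak-call matrices are mostly exact zeros, not dense
  noise. Blocks sit on deterministic consecutive index ranges, so noise-free
  output is seed-independent.
- `make_toy_genome()`: a battery of eight gene scenarios tiled 100 kb apart,
  firing every activity call and every exclusion rule at least once, with
  per-gene ground truth.
- `make_expression()`: expression exactly linear in a known subset of rows
  plus Gaussian noise.
- `make_loops()`: loops with one anchor on a promoter, remote anchors with
  exactly allocated enhancer classes (largest-remainder rounding of the
  requested fractions, then a seeded shuffle), known per-remote H3K27ac
  means and a single known CTCF argmax. Strong remotes also carry a weak
  segment so the precedence rule is exercised.

One master seed fans out to per-generator substreams, so adding a generator
never perturbs another's draws, and every generator is bit-reproducible.

These fixtures do **not** emulate read-level noise, peak-calling artifacts,
correlated experiments (replicate antibodies, co-binding factors), CAGE
count overdispersion, or the heavy-tailed loop-span distribution of real
ChIA-PET data. Passing the recovery tests therefore shows the procedures are
correct and stable under their stated model — planted structure of the
stated size and noise — not that real promoter clusters of any particular
biology will be recovered.

## Problem sizes and defaults used in the checks

The recovery experiments use a 30 × 300 matrix with three planted biclusters
(6 rows × 60/50/40 columns, signal 1.0, noise SD 0.2, background rate 0.02),
20 consensus runs, and five master seeds; column-label agreement with ground
truth is scored by the adjusted Rand index (direct-formula implementation,
cross-checked against an independent one). Feature recovery uses 20
experiments × 1000 promoters, four unit-weight predictors, noise SD 0.1,
20 seeds. These sizes give stable results while keeping the full suite in a
few minutes; the quadruple-count check runs the genuine 60-row enumeration.

## Known limitations

- The sparse-SVD engine assumes approximately constant-sign blocks on a low
  background, as produced by normalized occupancy; checkerboards of mixed
  sign within one layer are out of scope.
- Exact numerical equivalence with any particular published sparse-SVD
  biclustering package is not claimed; the engine behind the consensus is
  the documented variant above, and the consensus wrapper is tested
  engine-agnostically.
- Row sets may overlap between clusters only for the k-means engine; the
  SSVD engine resolves all overlaps.
- The elbow rule for k is a heuristic; for matrices without separated column
  groups it tends toward the lower end of `k_range`.
- `categorize()` applies a fixed precedence (intergenic > low > unassigned >
  cluster label) when categories co-occur; other precedences would change
  the marginal counts of comparison tables.
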