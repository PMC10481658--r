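---
title: "PromCoRe: models, parameters and design choices"
author: "PromCoRe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PromCoRe: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PromCoRe)
```

# Overview

PromCoRe asks how a cell-identity transcription-factor (TF) network is
organized, using promoter binding as the readout: TF cistromes are mined
for co-recruitment at TF-encoding gene promoters, the promoters are
clustered by binding pattern, and the clusters are characterized with
signal, expression-program and perturbation statistics. This vignette
explains the models behind each stage, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

# From peaks to the binding matrix

A cis-regulatory module (CRM) is a genomic region bound by at least two
distinct regulators. `mergePeaksToCrms()` pools all peaks and merges them
by single-linkage overlap, where overlap means at least one shared base:
book-ended (touching) peaks are *not* merged, matching the enrichment-peak
convention that adjacency is not co-occupancy. Strand is ignored
throughout, as ChIP peaks are unstranded. `mapCrmsToPromoters()` keeps one
record per gene whose active TSS (a width-1 interval at the summit base)
overlaps a CRM. Non-unique TSS–gene associations are discarded in both
directions — a TSS claimed by several genes and a gene with several
TSSs — because an ambiguous promoter cannot be attributed a binding
pattern. When one TSS overlaps several CRMs the bound-regulator sets are
unioned: the promoter is treated as a single binding locus. The resulting
`BindingMatrix` is binary, and every row sum is at least 2 by
construction.

Signal features follow enrichment-track semantics: per-promoter signal is
the maximum track value over the CRM interval, and bases not covered by
the track read as 0. The active-TSS filter keeps TSSs whose mean signal in
a ±500 bp window is at least twofold the control's window mean; a
pseudocount of 0.1 on both window means guards against division by zero.
H3K4me3 breadth is assigned only on actual overlap (distance zero between
TSS and domain); a TSS one base outside every domain stays unassigned.
Peak counting near TSSs uses a closed ±10 kb window by default.

# The toroidal SOM and cluster calling

`trainSOM()` implements an online self-organizing map with Euclidean
distance on the binary rows and a toroidal (wrap-around) grid: per axis,
the grid distance is `min(|d|, size − |d|)`. The torus avoids edge cells
with truncated neighborhoods, so no promoter pattern is pushed to a
boundary artifact. Training uses a bubble neighborhood (all cells within
the current radius move toward the presented row), a learning rate
decaying linearly from 0.05 to 0.01, and a radius decaying linearly from
`max(rows, cols)/2` to 1. None of these schedules is canonical; they are
conventional SOM defaults and are exposed as arguments. The grid side
defaults to `ceiling(sqrt(5 * sqrt(N)))`, a standard scale-adaptive
heuristic. Codebooks are initialized from randomly drawn data rows, which
keeps every codebook entry in [0, 1] under the convex updates.
Determinism: the presentation order and initialization are driven by one
seed, and best-matching-unit ties resolve to the lowest (row, col) in
lexicographic order.

Each cell's *prototype* is its codebook thresholded at 0.5 — the majority
vote of the cell's members at convergence. Promoter clusters are Ward cuts
(`hclust`, `ward.D2`, Euclidean) of the prototypes; cluster letters A, B,
… are assigned in ascending order of mean prototype sum, so later letters
mean more complex co-recruitment. The planar display of the toroidal map
unrolls at cell (0, 0); this is display-only.

**Homogeneity.** The number of clusters is guided by a homogeneity curve:
for each k, homogeneity is `1 − SS_within / SS_total` with squared
Euclidean distances to cluster centroids. Squared distances are a
deliberate choice: for nested hierarchical cuts, splitting a cluster can
never increase the within sum of squares (each child centroid is optimal
for its members), so the curve is guaranteed monotone non-decreasing and
reaches 1 at k = number of cells — properties a plain-distance version
does not guarantee. The suggested k is the elbow, computed as the interior
k maximizing the drop in marginal gain, `(f(k)−f(k−1)) − (f(k+1)−f(k))`;
this is the negated central second difference, which is the form that
detects where a rising concave curve flattens.

# Co-recruitment statistics

Tanimoto (Jaccard) distance between regulators is
`1 − |P_s ∩ P_t| / |P_s ∪ P_t|` over bound-promoter sets; a regulator
binding nothing is at distance 1 from everything and 0 from itself.
Classical (Torgerson) MDS double-centers the squared distances and scales
the top eigenvectors by the square root of their eigenvalues; negative
eigenvalues are truncated at zero, requested axes beyond the positive
spectrum are zero-padded, and each axis's first nonzero loading is made
positive so output is deterministic.

Core co-recruitment nodes are frequent itemsets under market-basket
semantics: transactions are promoters, and a regulator set is supported by
a promoter only when *all* members are simultaneously bound there. The
miner is a levelwise apriori search (candidates extended with
lexicographically later frequent items, pruned by anti-monotonicity) and
is tested against exhaustive subset enumeration. The default support
threshold is 0.5 of a cluster's promoters and the minimum set size is 2
(a "node" of one regulator is not a co-recruitment pattern); the maximum
size is clamped to the number of regulators present.

Distance correlation is the Székely sample statistic on doubly-centered
pairwise-distance matrices; the default is the biased V-statistic (the
convention of the commonly used implementations), with the U-centered
unbiased estimator available behind a flag. It is 0 by definition when
either distance variance vanishes.

# Expression programs

The multiple factor analysis (`mfa()`) treats each species' TF ×
cell-type table as one group: columns are centered and unit-scaled, each
group is weighted by the inverse of its first PCA eigenvalue — so a group
with more cell types or stronger internal structure cannot dominate the
compromise — and a global SVD of the weighted concatenation yields TF
scores. Two limiting behaviours pin the implementation down: duplicating
a group reproduces single-group PCA scores exactly (up to sign), and
duplicating a group's columns leaves the scores unchanged because the
weighting cancels the redundancy.

Programs are a Ward cut (k = 3) of the top five component scores. The
CTS/CTE/UBQ labels are assigned by an ordering statistic: the per-cluster
mean number of cell types in which a TF exceeds 25% of its own maximum
expression. This operationalizes "increasing number of cell types with
high expression" without fixing an absolute expression threshold; the 25%
level is arbitrary but only the *ordering* of the three clusters matters,
which is robust to it. No k-means consolidation is applied after the tree
cut.

Identity-connected TFs are selected among CTE/UBQ TFs by two conditions:
the focal cell (e.g. hepatocytes) ranks within the top 10 cells by
expression, and the log2 fold-difference
`log2((focal + ε)/(mean(others) + ε))` is positive, with ε = 0.01 on the
atlas's normalized scale to avoid infinities at zero expression. Rank
ties receive the average rank and the focal rank is then ceiled, which is
the conservative direction (a tie never sneaks a TF under the threshold).

# Matched controls and the representative set

Promoter-activity strata come from Ward clustering of
`log2(x + 0.01)`-transformed, z-scaled accessibility/acetylation/
expression features, with strata renumbered by ascending mean scaled
activity. Control sets are drawn without replacement within each stratum
to match the identity set's stratum counts exactly, 1,000 times by
default; identity genes are excluded from the candidate pool.

Each control set gets a test p-value (by default a two-sided Wilcoxon
rank-sum of identity versus control values), and the *representative*
set is the one at the mode of the p-value distribution. The mode is
computed on the exact discrete p-values (most frequent value, ties toward
the smaller one), not on a fixed-width histogram. The reason is a
property of rank tests: their p-values are discrete, and where
consecutive test statistics map to p-increments wider than a histogram
bin — the extremes of the distribution — every recurrence of a single
statistic piles into one bin, so a binned mode systematically lands at
the boundary rather than in the bulk. The discrete mode tracks the most
probable value of the test statistic, which for a unimodal statistic
distribution sits near the median; simulations in the test suite confirm
the representative's p-value then falls within the interquartile range of
the ensemble in ≥95% of runs under a clear planted shift. A binned
variant remains available via the `binWidth` argument.

Group tests: the rank-sum test enumerates exactly when both samples are
small (min n ≤ 10) and tie-free, and otherwise uses the normal
approximation with continuity correction; degenerate all-tied input
returns p = 1 with a warning. Odds ratios use the Haldane–Anscombe 0.5
correction only when a cell is zero, while the Fisher exact p is computed
on the uncorrected table; a zero margin yields NA. BH adjustment is the
standard step-up, applied per test family (per dataset/panel).

# Dedifferentiation projection

The reference differentiation series is modeled by a gene-centered PCA
(no unit scaling — genes with larger dynamic range *should* weigh more on
a differentiation axis), with PC1's sign oriented so the mature anchor
group scores positive. Perturbed studies are first batch-corrected
against the reference: per gene, the offset is the difference between the
target batch's anchor-sample mean and the reference anchor mean, and the
offsets are shrunk toward their grand mean with a normal empirical-Bayes
prior whose moments come from the offset distribution itself (method of
moments, sampling variance estimated from anchor replicates). Only
locations are corrected; variances are untouched. Two consequences are
worth noting: a constant planted offset is removed exactly (the prior
variance collapses to zero and the raw offsets are used), and adding a
constant to an entire batch leaves the corrected projection scores
unchanged. Projection is the dot product of centered samples with the PC1
loading, so projecting the reference itself reproduces its fitted scores.
The meta-analysis statistic across studies is the per-gene median log2
fold change, with a configurable minimum number of contributing studies.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the scale of a liver-type compendium: 49 regulator cistromes over 925
active TF-encoding promoters grouped into 7 planted co-binding clusters
of increasing regulator-set size; 13 planted identity TFs and 26 planted
identity-connected TFs taken from the most complex cluster; a two-species
expression atlas (39 + 126 cell types over a 1,009-TF universe) with
planted CTS/CTE/UBQ programs; 4 promoter-activity strata driving DHS,
H3K27ac and H3K4me3 tracks; perturbation studies with a planted −1 log2
group shift; and a 12-sample differentiation reference with 5 injury
studies carrying constant batch offsets. Values without an authoritative
source — noise standard deviations (0.25), the perturbation effect size,
the 20%/30%/50% CTS/CTE/UBQ split, peak width (200 bp), track bin width
(50 bp) — were fixed once at levels a practitioner would call realistic
for normalized functional-genomics data and are all exposed in
`syntheticConfig()`.

Noise models are deliberately the simplest ones matching the analysis's
implicit assumptions: Bernoulli flips for binding calls, i.i.d. Gaussian
(truncated at zero where the quantity is non-negative) for expression and
signal. Promoter loci sit on a single synthetic chromosome `chrS`, spaced
at least twice the widest emitted feature apart so features never merge
across promoters. Injured samples receive per-sample severity jitter
(uniformly 0.5–1.5 times the planted stage shift): injury severity varies
between animals, and a design where all injured samples share one exact
latent stage creates massive rank ties that no scoring method could
resolve. Every generator derives its own RNG stream from the root seed,
so stages are individually reproducible, and all outputs are pure
functions of (config, seed).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: peak-calling noise correlated with signal
strength, mappability and copy-number artifacts, overlapping/nested
promoters and bidirectional TSSs, phylogenetic correlation between the
species atlases, compositional or batch structure in expression beyond
constant offsets, and any read-level sequencing behaviour. Recovery
results on synthetic data are statements about the methods under their
own assumptions, not about biological truth.

# Problem sizes used in validation

Unit and property tests run at desk scale (tens of regulators, tens to
hundreds of promoters) chosen so each oracle comparison remains
exhaustive: itemsets are checked against full subset enumeration up to 12
regulators, Ward cuts against greedy objective minimization up to 8
points (on generic continuous coordinates, where the merge sequence is
unique), and interval operations against per-base O(n²) scans. Recovery
properties use 240 promoters × 24 regulators × 4 clusters over 10 seeds,
the full 1,009 × 165 atlas for program recovery, and 100 control-set
ensembles of 1,000 iterations each. The demo pipeline configuration uses
25 SOM epochs at the 925-promoter scale; convergence there is
well inside that budget because the planted blocks are strongly
separated.

# Known limitations

* The online SOM is a pure-R loop; it handles the package's intended
  scales (≈10³ promoters × 10²-cell grids) in seconds, but very large
  grids would warrant a compiled kernel or a batch-SOM variant.
* The itemset miner enumerates all frequent sets; with support far below
  0.5 on dense matrices the output is exponential by nature. The support
  threshold is the guard.
* The EB batch correction estimates per-gene sampling variance from
  anchor replicates; with a single anchor per batch it falls back to
  unshrunk offsets.
* `computeTau()` implements the standard specificity index; values
  reported elsewhere from other normalizations are not directly
  comparable.
* MDS reports zero-padded axes when the requested dimensionality exceeds
  the positive eigenvalue count; downstream code should check the
  returned spread before interpreting higher axes.
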