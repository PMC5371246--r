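---
title: "Clustering dropout-afflicted scRNA-seq data by implicit imputation"
author: "cidrclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering dropout-afflicted scRNA-seq data by implicit imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-cell RNA-seq count tables are riddled with *dropouts*: transcripts
that are present in a cell but observed as zero (or near zero) because
amplification failed during reverse transcription. When cells are compared
with plain Euclidean geometry — as in standard PCA — the terms where one
cell reports a zero and the other a large value inflate distances, and
they do so most severely for cell populations with many lowly expressed
genes. The inflation is noise, not signal, and it can swamp the real
between-type structure.

`cidrclust` implements the CIDR approach: instead of estimating dropout
values explicitly, it adjusts the *dissimilarity* between every pair of
cells, feature by feature, using a data-set-wide estimate of how likely a
value of a given magnitude is to be a dropout. The adjusted dissimilarity
matrix is then embedded by principal coordinate analysis (PCoA, classical
multidimensional scaling) and clustered hierarchically.

# The procedure

The pipeline (`run_cidr()`) has five stages, each independently callable.

**1. Transform and threshold.** Counts are scaled to tags per million and
log-transformed, `log2(TPM + 1)` by default (the base and pseudocount are
configurable; with pseudocount 1 a zero count maps exactly to 0). For each
cell, `find_dropout_threshold()` estimates the density of its logTPM
values (Epanechnikov kernel, rule-of-thumb `nrd0` bandwidth times an
`adjust` multiplier) and places a threshold $T_i$ at the density minimum
between the zero peak — the leftmost mode — and the next mode. Entries
below $T_i$ are *dropout candidates*; entries at or above it are
*expressed*. Candidates deliberately include true low or absent
expression, not only genuine dropouts. For robustness the per-cell
thresholds are winsorized at their outer deciles, and a median-of-subset
option can share one threshold across all cells.

**2. Estimate the dropout probability.** For every feature we record its
empirical dropout rate and the mean of its expressed entries. Pooling all
features, `fit_dropout_logistic()` fits the decreasing logistic

$$\hat P(u) = \frac{1}{1 + e^{a(u - b)}}, \qquad a > 0,$$

by non-linear least squares (Levenberg–Marquardt with a positivity bound
on $a$; starting values $a = 1$, $b$ = median expressed level). One global
$\hat P$ is shared by all genes and cells — the working assumption is that
most dropout candidates genuinely are dropouts, so pooling borrows
strength across the whole data set.

**3. Implicit pairwise imputation.** For a pair of cells and a feature
where exactly one value is a candidate, the candidate is replaced by the
weighted mean $W(o)\,o + (1 - W(o))\,o^{cand}$, where $o$ is the expressed
partner's value. By default $W$ is the step simplification of $\hat P$:
$W(u) = 1$ when $\hat P(u) > T_W$ (default $T_W = 0.5$), i.e. when $u$
lies below the *imputation weighting threshold* $u^\* = \hat
P^{-1}(T_W)$; the `variant = "logistic"` option uses $\hat P(o)$ itself as
the weight. When both values are candidates, both are treated as zero.
Imputed values are pair-local and never written back — the same entry is
imputed differently in every pairing, which is why the imputation is
called implicit. The dissimilarity is the Euclidean norm of the imputed
differences. It generally violates the triangle inequality, which is
acceptable for PCoA and can be repaired with the Cailliez additive
constant (`cailliez_correct()`) when a downstream method needs a metric.

Internally `cidr_dissimilarity()` does not loop over pairs: for both
weighting variants the squared dissimilarity factorizes exactly into a
handful of feature-contracting cross-products (the per-entry weight is a
product of a per-cell-i and a per-cell-j term), so the whole matrix is a
few BLAS calls with the same $O(\text{cells}^2 \times \text{features})$
arithmetic as the literal loop. The test suite verifies entrywise
agreement with a literal `impute_pair()` double loop.

**4. Embed.** PCoA of the dissimilarity matrix (`cidr_pcoa()`). Negative
eigenvalues may occur; they carry no coordinates and are excluded from the
variation proportions. The number of coordinates carried forward is chosen
by `select_n_pc()`: positive eigenvalues are grouped by walking their
consecutive differences, opening a new group whenever a difference exceeds
`cutoff_fraction` (default 0.1) of the largest difference; once the
current group exceeds `group_size_limit` (default 2) members, the total
size of the preceding groups is returned. The constants are package
choices — the rule, but not its constants, is fixed by the method — and if
the rule never fires (no dominant gap) a bounded default of 4 coordinates
is used and reported. With only two positive eigenvalues there is no
grouping evidence and the minimum of 1 is returned.

**5. Cluster.** Ward hierarchical clustering (`ward.D2`, which squares
its input distances internally) on the retained coordinates. The number
of clusters is selected from the Calinski–Harabasz index
$\mathrm{CH}(k) = \frac{\mathrm{tr}(B)/(k-1)}{\mathrm{tr}(W)/(n-k)}$
computed for $k = 2..k_{max}$ (default $k_{max} = \min(10, n-1)$): the
chosen $k$ is the sharpest concave bend of the curve, i.e. the most
negative central second difference, with ties toward smaller $k$. We also
evaluated a variant that returns the smallest $k$ after which all second
differences stay within a fraction of the largest one; on simulated data
with a sharply peaked CH curve it systematically overshot the peak by one,
so the sharpest-bend form is the default. A curve whose range is below 10%
of its mean is declared structureless and yields the minimum of 2 clusters
with a warning. Both $n_{PC}$ and the cluster count can be overridden
(`n_pc`, `n_cluster` in `cidr_config()`), mirroring the method's
user-facing parameters.

# Why imputation helps: expected-distance shrinkage

For one feature with true levels $x_1 \le x_2$ in two cells, true dropout
probability $P$ and estimated probability $\hat P$, the expected squared
contribution of the feature to the observed distance is

$$E(D_{data}) = (1-P(x_1))(1-P(x_2))(x_1-x_2)^2 + P(x_2)(1-P(x_1))x_1^2 +
P(x_1)(1-P(x_2))x_2^2,$$

and under pairwise imputation the two single-dropout terms acquire the
factors $(1-\hat P(x_1))^2$ and $(1-\hat P(x_2))^2$. Since these factors
are at most 1, imputation can only shrink the expectation
(`expected_distance_data()`, `expected_distance_cidr()`,
`shrinkage_rate()`). Monotonicity of the shrinkage *rate* — closer pairs
shrink proportionally more, which is what preserves cluster structure —
is hard to establish algebraically, so, as in the original computational
study, the suite asserts it numerically on $(x_1, x_2)$ grids over five
$(P, \hat P)$ families, including a step-function $\hat P$. The closed
forms themselves are checked against $10^6$-draw Monte-Carlo simulations
of the dropout and imputation process (3-s.e. bands).

The within/between-cluster summary (`wc_bc_summary()`) expresses the same
effect on data: on dropout-afflicted two-group simulations the imputed
dissimilarity raises the ratio of mean squared between-cluster to
within-cluster distance relative to no imputation, whereas imputing every
candidate to its feature's expressed mean (`irm_dissimilarity()`, the
row-mean baseline) shrinks between-cluster distances proportionally more
and dilutes the signal.

# The simulator

`simulate_dataset()` generates tag tables with known cell types. Per
type, an *expected library* of log2 tags is drawn from a log-normal
distribution (`lognormal_mu = 1.6`, `lognormal_sigma = 0.25` on the
meanlog/sdlog scale); the expected tag count of an entry $z$ is
$2^z - 1$, so $z = 0$ encodes a structural zero. Three feature classes
exist: null features share one draw across types; differentially
expressed features are shifted by `de_effect = 2` log2 units (sign drawn
per feature) in a random non-empty proper subset of types, clamped at
zero; marker features are positive in exactly one home type. Dropout
zeroes each entry independently with the decreasing logistic probability
$\pi(x) = 1/(1+e^{a(x-b)})$ of its expected level (`dropout_a = 1`,
`dropout_b = 6`), and Poisson noise then draws the final count from the
surviving expected tags — dropouts first, noise second.

The default configuration is three types of 50 cells with 20,000 null
features, 150 DE features and ten markers per type — deliberately few
markers, so the types are hard to separate. The free parameters (the
log-normal scale, effect size and dropout level, none of which are fixed
by the method itself) were calibrated once, with the shipped
`scripts/calibrate_simulator.R`, to three targets: a clearly bimodal
logTPM distribution with a dominant zero peak, an overall zero fraction
of roughly 50–70%, and a dropout level heavy enough that plain PCA with
the identical clustering procedure degrades badly while the
imputation-based pipeline still recovers the types. They are frozen in
`sim_config()` and are not adjusted per analysis.

What the simulator does *not* emulate: batch effects, doublets, UMI
counting, per-cell library-quality gradients, gene–gene correlation
beyond the type structure, or biological within-type variability (all
cells of a type share one expected library, so within-type variation
comes entirely from dropout and Poisson noise). Passing tests on these
data therefore demonstrate correct and robust behaviour of the algorithm
under its own generative assumptions, not performance on any particular
real data set.

# Numerical choices and degenerate inputs

* The FFT-based density estimate leaves ripple of order $10^{-17}$
  outside the Epanechnikov kernel's support; values below $10^{-6}$ of
  the maximum are flushed to zero before mode finding so the ripple
  cannot register as a mode (untreated, it can masquerade as a "zero
  peak" at a negative position and derail thresholding entirely).
* Ties in the valley search break toward the smaller expression value;
  a unimodal density falls back to the first grid point right of the
  peak where the density drops below 1% of the peak height, and a
  constant vector falls back to that constant with a warning.
* Threshold winsorization uses classical order statistics (the
  `floor(n/10)` smallest values are pulled up to the next order
  statistic, symmetrically at the top) rather than interpolated
  percentiles: the rank-based form leaves interior order statistics
  untouched and is exactly idempotent, which interpolated clamping is
  not.
* The dissimilarity stored and fed to PCoA is the unsquared distance
  (PCoA squares its input internally); a `pcoa_squared` flag supports
  the squared convention. Tiny negative squared distances from
  cancellation are clamped to zero and the matrix is symmetrized
  exactly before the eigendecomposition.
* Eigenvalues below $10^{-10}$ of the largest are treated as zero; the
  Cailliez constant comes from the standard companion eigenproblem and
  the corrected matrix is checked to have smallest eigenvalue above
  $-10^{-8}$.
* Everything after the simulator is deterministic: reruns on the same
  input are bit-identical, and coordinate sign flips (the inherent PCoA
  ambiguity) cannot change cluster labels because clustering uses
  Euclidean distances of the coordinates.

# Problem sizes

The shipped tests run the full study at its native scale — 20 replicates
of the 150-cell, 20,180-feature configuration — plus one scaled-up run
with 2,000 cells; the 10,000-cell scale is supported by the same code
path (the cross-product computation is the dominant cost, quadratic in
cells) but is not exercised by the default suite, which we sized to
complete on a single desktop core. Monte-Carlo oracles use $10^6$ draws.

# Limitations

* One global dropout model is shared by all genes and cells; data where
  dropout depends strongly on cell quality rather than expression level
  violate this.
* The dissimilarity is not a metric and is intended for PCoA; use the
  Cailliez option before methods that require metricity.
* The eigenvalue-gap and CH-bend selection rules are heuristics with
  package-chosen constants; inspect the exported variation and CH curves
  (`write_variation()`, the `ch_curve` element) and override `n_pc` /
  `n_cluster` when they disagree with the visible structure.
* Library-size filtering (default: drop cells under 10,000 tags) is the
  only quality control performed; gene-level filtering is available but
  off by default for the main pipeline.
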