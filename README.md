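# cidrclust

Clustering of single-cell RNA-seq count data in the presence of
dropouts, for anyone who wants fast, PCA-like dimensionality reduction
and clustering that does not treat every observed zero as a true zero.

## The method

Dropouts — expressed transcripts observed as zeros because amplification
failed — inflate Euclidean distances between cells and can bury the real
cell-type structure. CIDR (Clustering through Imputation and
Dimensionality Reduction) corrects the *distances* instead of the
values:

1. **Dropout candidates.** Each cell's `log2(TPM + 1)` distribution has a
   zero peak; a per-cell threshold `T_i` at the density minimum past that
   peak marks entries below it as dropout candidates.
2. **Dropout probability.** Pooling all features (empirical dropout rate
   vs mean expressed level), a decreasing logistic
   `P(u) = 1 / (1 + exp(a(u − b)))` is fitted by non-linear least squares.
3. **Implicit imputation.** For each cell pair and feature with exactly
   one candidate, the candidate is replaced by the weighted mean
   `W(o)·o + (1 − W(o))·o_cand`, where `o` is the expressed partner's
   value and `W` is the step simplification of `P` (weight 1 below
   `u* = P⁻¹(0.5)`, 0 above; the full logistic weight is available as a
   variant). Both-candidate pairs contribute zero. Imputed values are
   pair-local — no imputed matrix is ever materialized.
4. **PCoA** of the resulting dissimilarity matrix (negative eigenvalues
   allowed and discarded from variation proportions; optional Cailliez
   correction), with an eigenvalue-gap rule choosing the number of
   coordinates.
5. **Ward clustering** (`ward.D2`) on those coordinates, the number of
   clusters taken at the sharpest bend (second derivative) of the
   Calinski–Harabasz curve.

Imputation provably shrinks the expected pairwise distance, and shrinks
it proportionally more for closer pairs — the package ships the closed
forms and numerical checks (`expected_distance_data()`,
`expected_distance_cidr()`, `shrinkage_rate()`), the adjusted Rand
index, and the zero-inflated scRNA-seq simulator used for evaluation
(log-normal expected libraries, DE features, per-type markers, logistic
dropout, Poisson noise).

## Worked example

```r
library(cidrclust)

sim <- simulate_dataset(sim_config(seed = 7))   # 3 types x 50 cells
print(sim)
#> Simulated scRNA-seq data: 20180 features x 150 cells, 3 types
#>   zero fraction 0.67, dropout-zeroed fraction 0.67

fit <- run_cidr(sim$tags, cidr_config())
print(fit)
#> CIDR fit (step variant): 20180 features x 150 cells
#>   dropout-candidate fraction 0.67
#>   dropout model: a = 0.976, b = 6.415, u* = 6.415
#>   2 principal coordinates, 3 clusters

adjusted_rand_index(fit$clusters$labels, sim$true_labels)
#> 0.941
```

Two thirds of all entries are zeros, yet the fitted dropout model
(slope ~1, midpoint ~6.4 logTPM — recovering the simulator's true
dropout curve) lets the pipeline find the three planted cell types
almost perfectly; `fit$pcoa$coordinates` holds the embedding,
`fit$clusters$labels` the assignment, and every intermediate (thresholds,
candidate mask, tornado-plot data, dissimilarity matrix) is in `fit`.
Running `pca_baseline(sim$tags, cidr_config())` — plain PCA with the
identical clustering procedure — on the same data shows what the
imputation buys.

A command-line interface covers the same ground on files
(`inst/cli/cidr`):

```sh
cidr simulate --out sim/ --seed 7
cidr run --input sim/tags.tsv --out out/
cidr evaluate --labels out/clusters.tsv --truth sim/labels.tsv
cidr theory --out shrinkage.tsv
```

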