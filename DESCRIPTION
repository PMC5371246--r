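Package: cidrclust
Title: Clustering Through Implicit Imputation and Dimensionality Reduction
    for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clustering of single-cell RNA-seq count data in the presence of
    dropouts. Implements the CIDR approach: per-library dropout-candidate
    thresholds from the zero peak of the log-TPM distribution, a global
    logistic dropout-probability model fitted by non-linear least squares,
    a cell-cell dissimilarity computed with pair-local (implicit) imputation
    of dropout candidates, principal coordinate analysis with an optional
    Cailliez correction, and Ward hierarchical clustering with
    Calinski-Harabasz based selection of the number of clusters. Also ships
    a zero-inflated scRNA-seq simulator (log-normal expected libraries,
    differentially expressed features, cell-type markers, logistic dropout,
    Poisson noise), the adjusted Rand index, and numerical tools for the
    expected-distance-shrinkage analysis that motivates the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
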