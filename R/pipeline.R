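# End-to-end pipeline: logTPM -> dropout thresholds -> candidate mask ->
# feature statistics -> logistic dropout model -> implicit-imputation
# dissimilarity -> PCoA -> coordinate count -> Ward clustering.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults are
#' the method's defaults: step-function imputation with `t_w = 0.5`,
#' per-library winsorized thresholds, eigenvalue-gap coordinate selection
#' and Calinski-Harabasz cluster-number selection.
#'
#' @param min_library_size Cells with smaller library size are dropped
#'   (set 0 to disable).
#' @param log_base,pseudocount logTPM transform parameters.
#' @param bandwidth_adjust Bandwidth multiplier for threshold densities.
#' @param threshold_method `"per-library"` or `"median"`.
#' @param winsorize Winsorize per-library thresholds.
#' @param t_w Probability threshold of the step weighting function.
#' @param variant Dissimilarity variant: `"step"`, `"logistic"` or
#'   `"none"`.
#' @param pcoa_squared Feed squared dissimilarities to PCoA.
#' @param cailliez Apply the Cailliez correction before PCoA.
#' @param cutoff_fraction,group_size_limit Eigenvalue-gap rule constants
#'   (shared by coordinate-count and cluster-count selection).
#' @param n_pc Optional override of the number of principal coordinates.
#' @param n_cluster Optional override of the number of clusters.
#' @param k_max Largest candidate cluster number
#'   (default `min(10, cells - 1)`).
#' @return A list of class `"cidr_config"`.
#' @export
cidr_config <- function(min_library_size = 10000, log_base = 2,
                        pseudocount = 1, bandwidth_adjust = 1,
                        threshold_method = "per-library", winsorize = TRUE,
                        t_w = 0.5,
                        variant = c("step", "logistic", "none"),
                        pcoa_squared = FALSE, cailliez = FALSE,
                        cutoff_fraction = 0.1, group_size_limit = 2,
                        n_pc = NULL, n_cluster = NULL, k_max = NULL) {
  structure(
    list(min_library_size = min_library_size, log_base = log_base,
         pseudocount = pseudocount, bandwidth_adjust = bandwidth_adjust,
         threshold_method = threshold_method, winsorize = winsorize,
         t_w = t_w, variant = match.arg(variant),
         pcoa_squared = pcoa_squared, cailliez = cailliez,
         cutoff_fraction = cutoff_fraction,
         group_size_limit = group_size_limit,
         n_pc = n_pc, n_cluster = n_cluster, k_max = k_max),
    class = "cidr_config"
  )
}

#' Run the full clustering pipeline
#'
#' Executes all steps on a raw tag matrix and keeps every intermediate.
#' The pipeline is deterministic: the same tag matrix and configuration
#' give bit-identical results.
#'
#' @param tags Tag matrix (features x cells) of raw counts.
#' @param cfg A [cidr_config()].
#' @return Object of class `"cidr_fit"` with elements `logtpm`,
#'   `thresholds`, `mask`, `feature_stats`, `model`, `dissimilarity`,
#'   `pcoa`, `n_pc`, `clusters`, `cfg`.
#' @export
run_cidr <- function(tags, cfg = cidr_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  tags <- stage("input", as_tag_matrix(tags))
  if (cfg$min_library_size > 0)
    tags <- stage("filter", filter_libraries(tags, cfg$min_library_size))
  values <- stage("logtpm",
                  log_tpm(tags, base = cfg$log_base,
                          pseudocount = cfg$pseudocount))
  thresholds <- stage("thresholds",
    dropout_thresholds(values, method = cfg$threshold_method,
                       bandwidth_adjust = cfg$bandwidth_adjust,
                       winsorize = cfg$winsorize))
  mask <- stage("mask", candidate_mask(values, thresholds))
  fstats <- stage("feature_stats", dropout_feature_stats(values, mask))
  model <- if (cfg$variant == "none") NULL else
    stage("dropout_model", fit_dropout_logistic(fstats, t_w = cfg$t_w))
  d <- stage("dissimilarity",
             cidr_dissimilarity(values, mask, model, variant = cfg$variant))
  if (cfg$cailliez) d <- stage("cailliez", cailliez_correct(d))
  pc <- stage("pcoa",
              cidr_pcoa(if (cfg$pcoa_squared) d^2 else d,
                        squared = cfg$pcoa_squared))
  n_pc <- if (!is.null(cfg$n_pc)) as.integer(cfg$n_pc) else
    stage("n_pc", select_n_pc(pc$eigenvalues,
                              cutoff_fraction = cfg$cutoff_fraction,
                              group_size_limit = cfg$group_size_limit))
  clusters <- stage("cluster",
    cluster_cells(pc, n_pc = n_pc, n_cluster = cfg$n_cluster,
                  k_max = cfg$k_max))
  structure(
    list(logtpm = values, thresholds = thresholds, mask = mask,
         feature_stats = fstats, model = model, dissimilarity = d,
         pcoa = pc, n_pc = n_pc, clusters = clusters, cfg = cfg),
    class = "cidr_fit"
  )
}

#' @export
print.cidr_fit <- function(x, ...) {
  cat(sprintf("CIDR fit (%s variant): %d features x %d cells\n",
              x$cfg$variant, nrow(x$logtpm), ncol(x$logtpm)))
  cat(sprintf("  dropout-candidate fraction %.2f\n", mean(x$mask)))
  if (!is.null(x$model))
    cat(sprintf("  dropout model: a = %.3f, b = %.3f, u* = %.3f\n",
                x$model$a, x$model$b, x$model$u_star))
  cat(sprintf("  %d principal coordinates, %d clusters\n",
              x$n_pc, x$clusters$k))
  invisible(x)
}

#' Plain-PCA baseline
#'
#' Principal component analysis of the logTPM matrix (no imputation),
#' followed by the same coordinate-count selection and Ward/Calinski-
#' Harabasz clustering as the main pipeline — the standard-PCA comparator.
#'
#' @inheritParams run_cidr
#' @return Object of class `"cidr_fit"` (with `model`, `mask` absent and
#'   `dissimilarity = NULL`); `pcoa` holds the PCA scores and variances.
#' @export
pca_baseline <- function(tags, cfg = cidr_config()) {
  tags <- as_tag_matrix(tags)
  if (cfg$min_library_size > 0)
    tags <- filter_libraries(tags, cfg$min_library_size)
  values <- log_tpm(tags, base = cfg$log_base, pseudocount = cfg$pseudocount)
  pr <- stats::prcomp(t(unclass(values)), center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  tol <- 1e-10 * max(ev)
  pos <- which(ev > tol)
  pc <- structure(
    list(eigenvalues = ev,
         coordinates = pr$x[, pos, drop = FALSE],
         variation = ev[pos] / sum(ev[pos]),
         n_cells = ncol(values)),
    class = "cidr_pcoa"
  )
  n_pc <- if (!is.null(cfg$n_pc)) as.integer(cfg$n_pc) else
    select_n_pc(pc$eigenvalues, cutoff_fraction = cfg$cutoff_fraction,
                group_size_limit = cfg$group_size_limit)
  clusters <- cluster_cells(pc, n_pc = n_pc, n_cluster = cfg$n_cluster,
                            k_max = cfg$k_max)
  structure(
    list(logtpm = values, thresholds = NULL, mask = NULL,
         feature_stats = NULL, model = NULL, dissimilarity = NULL,
         pcoa = pc, n_pc = n_pc, clusters = clusters, cfg = cfg),
    class = "cidr_fit"
  )
}
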