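# Synthetic scRNA-seq generator with known cell types.
#
# For each cell type an expected library of log2 tags is drawn from a
# log-normal distribution; a small number of features are differentially
# expressed between types and each type carries a few private markers
# (positive in the home type, zero elsewhere). Per cell, entries are
# independently zeroed by dropout with a decreasing logistic probability of
# their expected level, and Poisson noise produces the final tag counts.

#' Simulator configuration
#'
#' Defaults reproduce the reference simulation: three cell types of 50
#' cells, 20,000 non-differentially expressed features, 150 differentially
#' expressed features and ten markers per type — a deliberately difficult
#' configuration with few markers. Expected log2 tags are drawn from a
#' log-normal distribution (`lognormal_mu`, `lognormal_sigma` are its
#' meanlog/sdlog); DE features are shifted by `de_effect` log2 units in a
#' random proper subset of types; dropout probability is
#' `pi(x) = 1 / (1 + exp(dropout_a * (x - dropout_b)))` of the expected
#' log2 tag `x`. The dropout parameters set the dropout level; the
#' defaults give an overall zero fraction around 60% and a clearly bimodal
#' logTPM distribution.
#'
#' @param n_types Number of cell types.
#' @param cells_per_type Cells per type; scalar or one value per type.
#' @param n_null_features Features identical in expectation across types.
#' @param n_de_features Differentially expressed features.
#' @param n_markers_per_type Private marker features per type.
#' @param lognormal_mu,lognormal_sigma meanlog/sdlog of the expected log2
#'   tag distribution.
#' @param de_effect Log2 shift applied to DE features in the affected types.
#' @param dropout_a,dropout_b Logistic dropout parameters (slope, midpoint
#'   in log2 tag units).
#' @param seed Integer seed; `simulate_dataset()` sets it before drawing.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_types = 3, cells_per_type = 50,
                       n_null_features = 20000, n_de_features = 150,
                       n_markers_per_type = 10,
                       lognormal_mu = 1.6, lognormal_sigma = 0.25,
                       de_effect = 2,
                       dropout_a = 1, dropout_b = 6,
                       seed = 1L) {
  if (length(cells_per_type) == 1L)
    cells_per_type <- rep(cells_per_type, n_types)
  stopifnot(length(cells_per_type) == n_types, all(cells_per_type >= 1),
            n_types >= 1, n_null_features >= 0, n_de_features >= 0,
            n_markers_per_type >= 0, de_effect >= 0, dropout_a > 0)
  structure(
    list(n_types = as.integer(n_types),
         cells_per_type = as.integer(cells_per_type),
         n_null_features = as.integer(n_null_features),
         n_de_features = as.integer(n_de_features),
         n_markers_per_type = as.integer(n_markers_per_type),
         lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
         de_effect = de_effect,
         dropout_a = dropout_a, dropout_b = dropout_b,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Expected libraries per cell type
#'
#' Draws the per-type expected log2 tag vectors. Non-DE features share one
#' draw across all types; each DE feature is shifted by `+/- de_effect` in
#' a random non-empty proper subset of types (clamped at zero); each
#' marker feature is positive in exactly its home type.
#'
#' Uses the current RNG state; [simulate_dataset()] seeds it from the
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @return Matrix of expected log2 tags, features x types, with a
#'   `feature_class` attribute (`"null"`, `"de"` or `"marker"`).
#' @export
make_expected_libraries <- function(cfg) {
  n_feat <- cfg$n_null_features + cfg$n_de_features +
    cfg$n_types * cfg$n_markers_per_type
  E <- matrix(0, n_feat, cfg$n_types)
  fclass <- rep(c("null", "de", "marker"),
                c(cfg$n_null_features, cfg$n_de_features,
                  cfg$n_types * cfg$n_markers_per_type))
  rl <- function(n) stats::rlnorm(n, cfg$lognormal_mu, cfg$lognormal_sigma)
  if (cfg$n_null_features > 0)
    E[fclass == "null", ] <- rl(cfg$n_null_features)
  if (cfg$n_de_features > 0) {
    base <- rl(cfg$n_de_features)
    sign <- sample(c(-1, 1), cfg$n_de_features, replace = TRUE)
    shifted <- matrix(FALSE, cfg$n_de_features, cfg$n_types)
    for (f in seq_len(cfg$n_de_features)) {
      repeat {
        s <- stats::runif(cfg$n_types) < 0.5
        if (any(s) && !all(s)) break
      }
      shifted[f, ] <- s
    }
    Ede <- matrix(base, cfg$n_de_features, cfg$n_types)
    Ede <- pmax(Ede + sign * cfg$de_effect * shifted, 0)
    E[fclass == "de", ] <- Ede
  }
  if (cfg$n_markers_per_type > 0) {
    mrows <- which(fclass == "marker")
    home <- rep(seq_len(cfg$n_types), each = cfg$n_markers_per_type)
    E[cbind(mrows, home)] <- rl(length(mrows))
  }
  rownames(E) <- paste0(fclass, "_", stats::ave(seq_len(n_feat), fclass,
                                                FUN = seq_along))
  colnames(E) <- paste0("type_", seq_len(cfg$n_types))
  attr(E, "feature_class") <- fclass
  E
}

#' Simulate dropouts
#'
#' Each entry of the per-cell expected library is independently zeroed
#' with probability `pi(x) = 1/(1 + exp(dropout_a (x - dropout_b)))` of
#' its expected log2 tag `x`. Uses the current RNG state.
#'
#' @param expected Matrix of expected log2 tags, features x cells.
#' @param cfg A [sim_config()].
#' @return List with `values` (expected log2 tags after dropout) and
#'   `dropout_truth` (logical mask of zeroed entries).
#' @export
apply_dropouts <- function(expected, cfg) {
  p <- 1 / (1 + exp(cfg$dropout_a * (expected - cfg$dropout_b)))
  truth <- matrix(stats::runif(length(expected)) < p,
                  nrow(expected), dimnames = dimnames(expected))
  values <- expected
  values[truth] <- 0
  list(values = values, dropout_truth = truth)
}

#' Add Poisson sampling noise
#'
#' Final tags are drawn Poisson with mean `2^x - 1` where `x` is the
#' (post-dropout) expected log2 tag; entries with `x = 0` stay exactly 0.
#' Uses the current RNG state.
#'
#' @param values Matrix of expected log2 tags after dropout.
#' @return Tag matrix of integer counts.
#' @export
add_poisson_noise <- function(values) {
  lambda <- pmax(2^values - 1, 0)
  tags <- matrix(stats::rpois(length(lambda), lambda),
                 nrow(lambda), dimnames = dimnames(lambda))
  as_tag_matrix(tags)
}

#' Simulate a full scRNA-seq data set
#'
#' Composes [make_expected_libraries()], [apply_dropouts()] and
#' [add_poisson_noise()] under the configuration's seed. Identical
#' configurations (including seed) give bit-identical data sets.
#'
#' @param cfg A [sim_config()].
#' @return List of class `"cidr_sim"`: `tags` (features x cells counts),
#'   `true_labels` (integer type per cell), `expected_libraries`
#'   (features x types log2 tags), `dropout_truth` (logical mask), `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  E <- make_expected_libraries(cfg)
  labels <- rep(seq_len(cfg$n_types), cfg$cells_per_type)
  expected <- E[, labels, drop = FALSE]
  colnames(expected) <- paste0("cell_", seq_along(labels))
  dropped <- apply_dropouts(expected, cfg)
  tags <- add_poisson_noise(dropped$values)
  names(labels) <- colnames(tags)
  structure(
    list(tags = tags, true_labels = labels, expected_libraries = E,
         dropout_truth = dropped$dropout_truth, cfg = cfg),
    class = "cidr_sim"
  )
}

#' @export
print.cidr_sim <- function(x, ...) {
  cat(sprintf("Simulated scRNA-seq data: %d features x %d cells, %d types\n",
              nrow(x$tags), ncol(x$tags), x$cfg$n_types))
  cat(sprintf("  zero fraction %.2f, dropout-zeroed fraction %.2f\n",
              mean(x$tags == 0), mean(x$dropout_truth)))
  invisible(x)
}
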