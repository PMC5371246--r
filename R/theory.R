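# Evaluation (adjusted Rand index, within/between-cluster distance
# summaries) and the expected-distance-shrinkage analysis.
#
# For a feature with true levels x1 and x2 in two cells, dropout
# probability P and estimated probability Phat, the expected squared
# contribution to the observed distance and to the imputed (CIDR) distance
# have closed forms; imputation multiplies the single-dropout terms by
# (1 - Phat(x))^2 <= 1, so the expected distance always shrinks, and the
# shrinkage rate is larger for closer pairs. Monotonicity is checked
# numerically on grids over several (P, Phat) families rather than proven.

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions of the
#' same items: 1 for identical partitions (up to label permutation),
#' expectation 0 under random labelling.
#'
#' @param labels_a,labels_b Partition labels, equal length.
#' @return The index value (at most 1).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n < 2L) stop("need at least two items")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Logistic dropout-probability function
#'
#' `P(x) = 1 / (1 + exp(a (x - b)))`, monotone decreasing for `a > 0`.
#'
#' @param a Slope (> 0).
#' @param b Midpoint.
#' @return A function of `x`.
#' @export
logistic_dropout_fn <- function(a, b) {
  force(a); force(b)
  function(x) 1 / (1 + exp(a * (x - b)))
}

#' Step dropout-probability function
#'
#' `P(x) = high` for `x < u_star`, `low` otherwise (defaults 1 and 0) —
#' the estimated-probability shape induced by the step weighting function.
#'
#' @param u_star Jump location.
#' @param high,low Values below/above the jump.
#' @return A function of `x`.
#' @export
step_dropout_fn <- function(u_star, high = 1, low = 0) {
  force(u_star); force(high); force(low)
  function(x) ifelse(x < u_star, high, low)
}

#' Expected observed squared distance under dropout
#'
#' For true levels `x1`, `x2` and dropout probability function `p`, the
#' expectation of the squared difference of the observed (dropout-
#' afflicted) values:
#' `(1-P(x1))(1-P(x2))(x1-x2)^2 + P(x2)(1-P(x1))x1^2 + P(x1)(1-P(x2))x2^2`.
#'
#' @param x1,x2 True expression levels (vectorized).
#' @param p Dropout probability function.
#' @return Expected squared distance contribution.
#' @export
expected_distance_data <- function(x1, x2, p) {
  p1 <- p(x1); p2 <- p(x2)
  (1 - p1) * (1 - p2) * (x1 - x2)^2 + p2 * (1 - p1) * x1^2 +
    p1 * (1 - p2) * x2^2
}

#' Expected imputed squared distance under dropout
#'
#' As [expected_distance_data()], but with the two single-dropout terms
#' damped by `(1 - p_hat(x1))^2` and `(1 - p_hat(x2))^2` — the effect of
#' pairwise imputation with estimated dropout probability `p_hat`.
#'
#' @inheritParams expected_distance_data
#' @param p_hat Estimated dropout probability function (may be a step).
#' @export
expected_distance_cidr <- function(x1, x2, p, p_hat) {
  p1 <- p(x1); p2 <- p(x2)
  (1 - p1) * (1 - p2) * (x1 - x2)^2 +
    p2 * (1 - p1) * (1 - p_hat(x1))^2 * x1^2 +
    p1 * (1 - p2) * (1 - p_hat(x2))^2 * x2^2
}

#' Expected rate of distance shrinkage
#'
#' `1 - E(D_cidr) / E(D_data)`; lies in `[0, 1]` whenever the expected
#' observed distance is positive, and `NA` where it is zero.
#'
#' @inheritParams expected_distance_cidr
#' @export
shrinkage_rate <- function(x1, x2, p, p_hat) {
  ed <- expected_distance_data(x1, x2, p)
  ec <- expected_distance_cidr(x1, x2, p, p_hat)
  ifelse(ed > 0, 1 - ec / ed, NA_real_)
}

#' Shrinkage grid report
#'
#' Evaluates the expected observed and imputed squared distances and the
#' shrinkage rate on a grid of `(x1, x2)` pairs.
#'
#' @param x1_grid,x2_grid Grid coordinates.
#' @inheritParams expected_distance_cidr
#' @return Data frame with columns `x1`, `x2`, `e_data`, `e_cidr`, `rate`.
#' @export
shrinkage_grid <- function(x1_grid, x2_grid, p, p_hat) {
  g <- expand.grid(x1 = x1_grid, x2 = x2_grid)
  g$e_data <- expected_distance_data(g$x1, g$x2, p)
  g$e_cidr <- expected_distance_cidr(g$x1, g$x2, p, p_hat)
  g$rate <- ifelse(g$e_data > 0, 1 - g$e_cidr / g$e_data, NA_real_)
  g
}

#' Within- and between-cluster squared distance summary
#'
#' Means of the squared dissimilarities over cell pairs within the same
#' cluster and across clusters. Singleton clusters contribute no
#' within-cluster pairs; with only singletons the within mean is `NA`.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param labels Cluster labels per cell (>= 2 clusters).
#' @return List with `mean_wc_sq` and `mean_bc_sq`.
#' @export
wc_bc_summary <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(labels) != n) stop("one label per cell required")
  if (length(unique(labels)) < 2L) stop("need at least two clusters")
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  wc <- d[ut & same]^2
  bc <- d[ut & !same]^2
  list(mean_wc_sq = if (length(wc)) mean(wc) else NA_real_,
       mean_bc_sq = mean(bc))
}
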