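# Dropout-candidate detection and the global dropout-probability model.
#
# Each cell gets a threshold T separating the zero peak of its logTPM
# distribution from the expressed modes; entries below T are dropout
# candidates. Pooling (empirical dropout rate, mean expressed level) across
# features, a decreasing logistic P(u) is fitted by non-linear least squares
# and shared by all cells.

#' Per-cell dropout-candidate threshold
#'
#' Finds the minimum of the kernel density estimate between the leftmost
#' mode (the zero peak) and the next mode of a cell's logTPM distribution.
#' The Epanechnikov kernel is used with the rule-of-thumb (`nrd0`) bandwidth
#' scaled by `bandwidth_adjust`. When the density estimate is unimodal the
#' threshold falls back to the first grid point, right of the zero peak,
#' where the density drops below 1% of the peak height.
#'
#' @param cell_values Numeric vector of logTPM values for one cell.
#' @param bandwidth_adjust Multiplier on the rule-of-thumb bandwidth.
#' @return A single threshold on the logTPM scale.
#' @export
find_dropout_threshold <- function(cell_values, bandwidth_adjust = 1) {
  x <- as.numeric(cell_values)
  if (length(x) < 2L) stop("need at least two values to estimate a density")
  if (diff(range(x)) == 0) {
    warning("constant expression vector; using the constant as the threshold")
    return(x[1L])
  }
  d <- stats::density(x, bw = "nrd0", adjust = bandwidth_adjust,
                      kernel = "epanechnikov", n = 512)
  y <- d$y
  # the FFT-based estimate leaves O(1e-17) ripple outside the kernel
  # support; flush it to zero so it cannot masquerade as a mode
  y[y < 1e-6 * max(y)] <- 0
  n <- length(y)
  # interior local maxima plus the two boundary points
  is_max <- c(y[1L] > y[2L],
              y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n],
              y[n] > y[n - 1L])
  modes <- which(is_max & y > 0)
  if (length(modes) == 0L) modes <- which.max(y)
  if (length(modes) >= 2L) {
    m1 <- modes[1L]
    m2 <- modes[2L]
    between <- (m1 + 1L):(m2 - 1L)
    if (length(between) == 0L) between <- m1
    # which.min takes the first minimum, i.e. ties break toward smaller values
    return(d$x[between[which.min(y[between])]])
  }
  # unimodal: first point right of the peak below 1% of the peak height
  m1 <- modes[1L]
  low <- which(y < 0.01 * y[m1])
  low <- low[low > m1]
  message("unimodal density; falling back to the 1%-of-peak threshold")
  if (length(low) == 0L) return(d$x[n])
  d$x[low[1L]]
}

#' Winsorize per-cell thresholds
#'
#' The bottom and top deciles of the thresholds are pulled in to the 10th-
#' and 90th-percentile values. Percentiles are taken as order statistics
#' (classical winsorization: the `floor(n/10)` smallest values become the
#' next value up, and symmetrically at the top), which leaves the interior
#' order statistics unchanged and makes the operation exactly idempotent.
#'
#' @param raw Numeric vector of per-cell thresholds.
#' @return Winsorized thresholds, same length and names.
#' @export
winsorize_thresholds <- function(raw) {
  n <- length(raw)
  if (n < 1L) stop("no thresholds supplied")
  k <- floor(0.1 * n)
  s <- sort(raw)
  pmin(pmax(raw, s[k + 1L]), s[n - k])
}

#' Dropout-candidate thresholds for all cells
#'
#' Computes `find_dropout_threshold` per cell. With
#' `method = "per-library"` each cell keeps its own (winsorized) threshold;
#' with `method = "median"` thresholds are computed for `subset` only and
#' their median is broadcast to every cell.
#'
#' @param values logTPM matrix (features x cells).
#' @param method `"per-library"` or `"median"`.
#' @param subset Cells (indices or names) used under `method = "median"`;
#'   defaults to all cells.
#' @param bandwidth_adjust Passed to [find_dropout_threshold()].
#' @param winsorize Winsorize per-library thresholds (default `TRUE`).
#' @return Named numeric vector of thresholds, one per cell, with
#'   attributes `method` and `winsorized`.
#' @export
dropout_thresholds <- function(values, method = c("per-library", "median"),
                               subset = NULL, bandwidth_adjust = 1,
                               winsorize = TRUE) {
  method <- match.arg(method)
  if (method == "median") {
    if (is.null(subset)) subset <- seq_len(ncol(values))
    sub <- values[, subset, drop = FALSE]
    if (ncol(sub) == 0L) stop("empty cell subset")
    raw <- apply(sub, 2L, find_dropout_threshold,
                 bandwidth_adjust = bandwidth_adjust)
    t <- rep(stats::median(raw), ncol(values))
    winsorized <- FALSE
  } else {
    t <- apply(values, 2L, find_dropout_threshold,
               bandwidth_adjust = bandwidth_adjust)
    if (winsorize) t <- winsorize_thresholds(t)
    winsorized <- winsorize
  }
  names(t) <- colnames(values)
  attr(t, "method") <- method
  attr(t, "winsorized") <- winsorized
  t
}

#' Median threshold from a cell subset
#'
#' Convenience wrapper for the shared-threshold option: the median of the
#' thresholds computed on `subset` is used for all cells of `values`.
#'
#' @inheritParams dropout_thresholds
#' @export
median_threshold <- function(values, subset = NULL, bandwidth_adjust = 1) {
  dropout_thresholds(values, method = "median", subset = subset,
                     bandwidth_adjust = bandwidth_adjust)
}

#' Dropout-candidate mask
#'
#' An entry is a dropout candidate when its value is strictly below its
#' cell's threshold; entries at or above the threshold are expressed.
#'
#' @param values logTPM matrix (features x cells).
#' @param thresholds Per-cell thresholds (recycled if scalar).
#' @return Logical matrix, `TRUE` marking dropout candidates.
#' @export
candidate_mask <- function(values, thresholds) {
  if (length(thresholds) == 1L) thresholds <- rep(thresholds, ncol(values))
  if (length(thresholds) != ncol(values))
    stop("one threshold per cell required")
  mask <- sweep(unclass(values), 2L, thresholds, "<")
  dimnames(mask) <- dimnames(values)
  mask
}

#' Per-feature dropout statistics
#'
#' For every feature: the empirical dropout rate (fraction of cells in
#' which it is a candidate), the mean of its expressed (non-candidate)
#' entries, and the number of expressed entries. Features expressed in no
#' cell get `NA` for the mean and are excluded from the regression input.
#'
#' @param values logTPM matrix.
#' @param mask Candidate mask from [candidate_mask()].
#' @return `data.frame` with columns `feature`, `dropout_rate`,
#'   `mean_expressed`, `n_expressed`.
#' @export
dropout_feature_stats <- function(values, mask) {
  stopifnot(all(dim(values) == dim(mask)))
  n_expressed <- rowSums(!mask)
  sums <- rowSums(unclass(values) * !mask)
  mean_expressed <- ifelse(n_expressed > 0, sums / n_expressed, NA_real_)
  data.frame(
    feature = if (is.null(rownames(values)))
      paste0("feature_", seq_len(nrow(values))) else rownames(values),
    dropout_rate = rowMeans(mask),
    mean_expressed = mean_expressed,
    n_expressed = n_expressed,
    row.names = NULL
  )
}

#' Construct a dropout model
#'
#' The fitted dropout-probability function is the decreasing logistic
#' `P(u) = 1 / (1 + exp(a * (u - b)))` with slope `a > 0` and midpoint `b`.
#' Its step simplification `W(u)` is 1 where `P(u) > t_w` (i.e. below the
#' imputation weighting threshold `u_star = P^{-1}(t_w)`) and 0 elsewhere.
#'
#' @param a Logistic slope, must be positive.
#' @param b Logistic midpoint, logTPM units.
#' @param t_w Probability threshold of the step function (default 0.5).
#' @param rss Optional residual sum of squares of the fit.
#' @param n_features Optional number of features used in the fit.
#' @return Object of class `"dropout_model"`.
#' @export
dropout_model <- function(a, b, t_w = 0.5, rss = NA_real_,
                          n_features = NA_integer_) {
  if (!is.finite(a) || a <= 0) stop("slope a must be positive")
  if (t_w <= 0 || t_w >= 1) stop("t_w must lie in (0, 1)")
  structure(
    list(a = a, b = b, t_w = t_w,
         u_star = b + log(1 / t_w - 1) / a,
         rss = rss, n_features = n_features),
    class = "dropout_model"
  )
}

#' @export
print.dropout_model <- function(x, ...) {
  cat("Dropout model P(u) = 1 / (1 + exp(a (u - b)))\n")
  cat(sprintf("  a = %.4f, b = %.4f, T_W = %.2f, u* = %.4f\n",
              x$a, x$b, x$t_w, x$u_star))
  if (is.finite(x$rss))
    cat(sprintf("  fitted on %d features, RSS = %.4f\n", x$n_features, x$rss))
  invisible(x)
}

#' Evaluate the fitted dropout probability
#'
#' @param object A `dropout_model`.
#' @param u Expression levels (logTPM).
#' @param ... Unused.
#' @return `P(u)`, values in (0, 1), strictly decreasing in `u`.
#' @export
predict.dropout_model <- function(object, u, ...) {
  1 / (1 + exp(object$a * (u - object$b)))
}

#' Step imputation weighting function
#'
#' `W(u) = 1` when `P(u) > t_w` (equivalently `u < u_star`), else 0.
#'
#' @param model A `dropout_model`.
#' @param u Expression levels.
#' @export
impute_weight <- function(model, u) {
  as.numeric(u < model$u_star)
}

#' Fit the decreasing logistic dropout model
#'
#' Non-linear least squares of empirical dropout rate against mean
#' expressed level over features, with the slope constrained positive.
#' Starting values are `a = 1`, `b = median(mean_expressed)`.
#'
#' @param stats Data frame from [dropout_feature_stats()].
#' @param t_w Probability threshold for the step simplification.
#' @return A fitted [dropout_model()].
#' @export
fit_dropout_logistic <- function(stats, t_w = 0.5) {
  use <- stats$n_expressed >= 1 & is.finite(stats$mean_expressed)
  u <- stats$mean_expressed[use]
  r <- stats$dropout_rate[use]
  if (length(u) < 3L) stop("need at least 3 features with expressed entries")
  if (diff(range(u)) <= 0) stop("mean expressed levels span no range")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ 1 / (1 + exp(a * (u - b))),
      start = list(a = 1, b = stats::median(u)),
      lower = c(a = 1e-6, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("logistic dropout fit failed to converge: ",
                             conditionMessage(e))
  )
  cf <- stats::coef(fit)
  dropout_model(a = unname(cf["a"]), b = unname(cf["b"]), t_w = t_w,
                rss = sum(stats::residuals(fit)^2),
                n_features = length(u))
}
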