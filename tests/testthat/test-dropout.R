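test_that("threshold falls in the inter-mode valley of a bimodal mixture", {
  # analytic mixture: 0.6 N(0.5, 0.4) + 0.4 N(8, 0.8); its density is known
  # exactly, so the valley can be located by brute-force grid minimization
  f <- function(x) 0.6 * dnorm(x, 0.5, 0.4) + 0.4 * dnorm(x, 8, 0.8)
  grid <- seq(0.5, 8, by = 0.001)
  valley <- grid[which.min(f(grid))]
  set.seed(101)
  x <- pmax(c(rnorm(180, 0.5, 0.4), rnorm(120, 8, 0.8)), 0)
  thr <- find_dropout_threshold(x)
  expect_lt(abs(thr - valley), 1.5)
  # the threshold sits where the true density is negligible
  expect_lt(f(thr), 0.05 * f(8))

  # robustness to the bandwidth multiplier: all inside the same valley
  thrs <- sapply(c(0.5, 1, 1.5), function(adj)
    find_dropout_threshold(x, bandwidth_adjust = adj))
  expect_true(all(thrs > 2 & thrs < 7))
})

test_that("degenerate expression vectors fall back with a warning", {
  expect_warning(t0 <- find_dropout_threshold(rep(0, 50)), "constant")
  expect_identical(t0, 0)
  expect_error(find_dropout_threshold(1), "at least two")
  # unimodal but non-constant: falls back to the 1%-of-peak rule
  set.seed(3)
  expect_message(t1 <- find_dropout_threshold(rnorm(200, 5, 0.5),
                                               bandwidth_adjust = 3),
                 "unimodal")
  expect_gt(t1, 5)
})

test_that("winsorization pins the outer deciles and is idempotent", {
  w <- winsorize_thresholds(1:10)
  # order-statistic deciles of 1..10 are the 2nd and 9th values
  expect_equal(w, c(2, 2:9, 9))
  expect_equal(winsorize_thresholds(w), w)
  expect_equal(winsorize_thresholds(rep(3, 7)), rep(3, 7))
  # interior order statistics unchanged
  set.seed(9)
  r <- rnorm(40)
  w2 <- winsorize_thresholds(r)
  s <- sort(r)
  expect_equal(sort(w2)[6:35], s[6:35])
  expect_true(all(w2 >= sort(r)[5] & w2 <= sort(r)[36]))
})

test_that("median thresholding broadcasts the subset median", {
  set.seed(21)
  v <- small_logtpm_fixture(seed = 21, n_feat = 200, n_cells = 10)
  t_med <- median_threshold(v, subset = 1:4)
  expect_identical(length(unique(as.numeric(t_med))), 1L)
  per_cell <- apply(v[, 1:4], 2, find_dropout_threshold)
  expect_equal(unname(t_med[1]), median(per_cell))
  # one-cell subset broadcasts that cell's threshold
  t_one <- median_threshold(v, subset = 2)
  expect_equal(unname(t_one[5]), unname(per_cell[2]))
})

test_that("candidate mask uses strict less-than per cell", {
  v <- matrix(c(0, 1, 2, 3), 2, 2)
  m <- candidate_mask(v, c(1, 3))
  expect_identical(unname(m), matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  # entry exactly at the threshold counts as expressed
  expect_false(m[2, 2])
  # zero threshold flags nothing
  expect_false(any(candidate_mask(v, c(0, 0))))
  # brute-force agreement on a random fixture
  set.seed(14)
  v2 <- small_logtpm_fixture(14, 50, 6)
  th <- runif(6, 1, 4)
  m2 <- candidate_mask(v2, th)
  ref <- matrix(FALSE, 50, 6)
  for (k in 1:50) for (i in 1:6) ref[k, i] <- v2[k, i] < th[i]
  expect_identical(unname(m2), ref)
})

test_that("feature statistics match hand computation", {
  v <- matrix(c(0, 0, 4, 6,
                5, 6, 7, 8,
                0, 0, 0, 0), 3, 4, byrow = TRUE)
  mask <- candidate_mask(v, rep(1, 4))
  fs <- dropout_feature_stats(v, mask)
  expect_equal(fs$dropout_rate, c(0.5, 0, 1))
  expect_equal(fs$mean_expressed[1], 5)
  expect_equal(fs$mean_expressed[2], 6.5)
  expect_true(is.na(fs$mean_expressed[3]))
  expect_equal(fs$n_expressed, c(2, 4, 0))
})

test_that("logistic fit recovers known parameters", {
  u <- seq(0.2, 6, length.out = 80)
  rate <- 1 / (1 + exp(1.5 * (u - 2)))
  stats <- data.frame(feature = seq_along(u), dropout_rate = rate,
                      mean_expressed = u, n_expressed = 5L)
  m <- fit_dropout_logistic(stats)
  expect_equal(m$a, 1.5, tolerance = 1e-3)
  expect_equal(m$b, 2, tolerance = 1e-3)
  # T_W = 0.5 puts the imputation weighting threshold at the midpoint
  expect_equal(m$u_star, m$b)
  # and a different T_W moves it by the logistic inverse
  m2 <- fit_dropout_logistic(stats, t_w = 0.2)
  expect_equal(predict(m2, m2$u_star), 0.2, tolerance = 1e-6)
})

test_that("logistic fit is stable under observation noise", {
  u <- seq(0.2, 6, length.out = 80)
  truth <- 1 / (1 + exp(1.5 * (u - 2)))
  est <- t(sapply(1:20, function(s) {
    set.seed(s)
    r <- pmin(pmax(truth + rnorm(80, 0, 0.02), 0), 1)
    m <- fit_dropout_logistic(data.frame(feature = seq_along(u),
                                         dropout_rate = r,
                                         mean_expressed = u,
                                         n_expressed = 5L))
    c(m$a, m$b)
  }))
  expect_lt(max(abs(est[, 1] - 1.5)), 0.3)
  expect_lt(max(abs(est[, 2] - 2)), 0.1)
})

test_that("fitted dropout probability is strictly decreasing with one step", {
  m <- dropout_model(a = 1.2, b = 3)
  grid <- seq(0, 10, by = 0.05)
  p <- predict(m, grid)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
  w <- impute_weight(m, grid)
  expect_true(all(w %in% c(0, 1)))
  expect_identical(which(diff(w) != 0), which(grid < m$u_star)[sum(grid < m$u_star)])
  # W(u) = 1 exactly where P(u) > T_W
  expect_identical(w, as.numeric(p > 0.5))
})

test_that("mask is reproducible from values and thresholds", {
  v <- small_logtpm_fixture(77, 40, 12)
  th <- dropout_thresholds(v)
  m1 <- candidate_mask(v, th)
  m2 <- candidate_mask(v, th)
  expect_identical(m1, m2)
  expect_identical(length(th), ncol(v))
  expect_true(attr(th, "winsorized"))
})
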