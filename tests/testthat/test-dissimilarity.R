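test_that("pairwise imputation follows the weighted-mean rules", {
  m <- dropout_model(a = 1, b = 3)   # u_star = 3

  # both candidates: both set to zero regardless of raw values
  r <- impute_pair(0.3, 0.8, TRUE, TRUE, m)
  expect_equal(c(r$o_ki, r$o_kj), c(0, 0))

  # one candidate, expressed partner below u_star: full borrowing (W = 1)
  r <- impute_pair(0.2, 1, TRUE, FALSE, m)
  expect_equal(r$o_ki, 1)
  expect_equal(r$o_kj, 1)

  # one candidate, expressed partner above u_star: untouched (W = 0)
  r <- impute_pair(0.2, 5, TRUE, FALSE, m)
  expect_equal(r$o_ki, 0.2)

  # neither candidate: no imputation
  r <- impute_pair(2, 7, FALSE, FALSE, m)
  expect_equal(c(r$o_ki, r$o_kj), c(2, 7))

  # logistic weight at the midpoint averages the two values
  r <- impute_pair(1, m$b, TRUE, FALSE, m, use_step = FALSE)
  expect_equal(r$o_ki, (1 + m$b) / 2)
})

test_that("worked 2-cell example reproduces the hand trace", {
  v <- matrix(c(0, 0, 4,
                5, 1, 4), 3, 2)
  mask <- candidate_mask(v, c(1, 1))
  m <- dropout_model(a = 1, b = 3)   # u_star = 3
  d <- cidr_dissimilarity(v, mask, m, variant = "step")
  # feature 1: W(5) = 0 keeps (0,5); feature 2: W(1) = 1 borrows to (1,1);
  # feature 3: both expressed -> sqrt(25 + 0 + 0) = 5
  expect_equal(d[1, 2], 5)
  expect_equal(d[2, 1], 5)
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)
  # swapping the two cells leaves the dissimilarity unchanged
  d2 <- cidr_dissimilarity(v[, 2:1], mask[, 2:1], m, variant = "step")
  expect_equal(d2[1, 2], d[1, 2])
})

test_that("no candidates reduces every variant to plain Euclidean distance", {
  set.seed(31)
  v <- matrix(runif(60, 1, 9), 10, 6)
  mask <- matrix(FALSE, 10, 6)
  m <- dropout_model(a = 1, b = 3)
  ref <- as.matrix(dist(t(v)))
  for (variant in c("step", "logistic")) {
    d <- cidr_dissimilarity(v, mask, m, variant = variant)
    expect_equal(unname(d), unname(ref), tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(unname(irm_dissimilarity(v, mask)), unname(ref), ignore_attr = TRUE)
})

test_that("cross-product computation matches the literal pair loop", {
  set.seed(57)
  v <- small_logtpm_fixture(57, 40, 9)
  mask <- candidate_mask(v, dropout_thresholds(v))
  m <- dropout_model(a = 1.3, b = 5)
  for (use_step in c(TRUE, FALSE)) {
    variant <- if (use_step) "step" else "logistic"
    d <- cidr_dissimilarity(v, mask, m, variant = variant)
    ref <- naive_cidr_dist(v, mask, m, use_step = use_step)
    expect_equal(unname(d), ref, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unname(d), unname(t(d)), ignore_attr = TRUE)
    expect_true(all(d >= 0))
  }
})

test_that("logistic variant converges to the step variant for steep fits", {
  set.seed(58)
  v <- small_logtpm_fixture(58, 30, 7)
  mask <- candidate_mask(v, rep(2, 7))
  step_m <- dropout_model(a = 1, b = 4)
  steep_m <- dropout_model(a = 500, b = 4)   # near-step logistic, same jump
  d_step <- cidr_dissimilarity(v, mask, step_m, variant = "step")
  d_logi <- cidr_dissimilarity(v, mask, steep_m, variant = "logistic")
  expect_equal(unname(d_logi), unname(d_step), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("row-mean imputation uses expressed feature means", {
  v <- matrix(c(0, 4, 6,
                2, 5, 8), 3, 2, byrow = FALSE)
  v <- matrix(c(0, 2,
                4, 5,
                6, 8), 3, 2, byrow = TRUE)
  mask <- matrix(c(TRUE, FALSE,
                   FALSE, FALSE,
                   FALSE, FALSE), 3, 2, byrow = TRUE)
  d <- irm_dissimilarity(v, mask)
  # candidate (feature 1, cell 1) imputed to its only expressed value 2
  expect_equal(d[1, 2], sqrt(0 + 1 + 4))
  # a fully-candidate feature imputes to zero with a message
  mask2 <- rbind(c(TRUE, TRUE), mask[2:3, ])
  expect_message(d2 <- irm_dissimilarity(v, mask2), "no expressed")
  expect_equal(d2[1, 2], sqrt(0 + 1 + 4))
})

test_that("imputation sharpens the two-cluster contrast more within than between", {
  # dropout-afflicted two-group data: the imputed dissimilarity should
  # increase the between/within mean-squared-distance ratio relative to
  # no imputation, and row-mean imputation should shrink between-cluster
  # distances proportionally more than pairwise imputation does
  ratios <- sapply(1:20, function(s) {
    cfg <- sim_config(n_types = 2, cells_per_type = 15,
                      n_null_features = 800, n_de_features = 60,
                      n_markers_per_type = 5, seed = s)
    sim <- simulate_dataset(cfg)
    v <- log_tpm(sim$tags, )
    mask <- candidate_mask(v, dropout_thresholds(v))
    model <- fit_dropout_logistic(dropout_feature_stats(v, mask))
    lab <- sim$true_labels
    d_cidr <- cidr_dissimilarity(v, mask, model)
    d_none <- cidr_dissimilarity(v, mask, model, variant = "none")
    d_irm <- irm_dissimilarity(v, mask)
    s_cidr <- wc_bc_summary(d_cidr, lab)
    s_none <- wc_bc_summary(d_none, lab)
    s_irm <- wc_bc_summary(d_irm, lab)
    c(cidr = s_cidr$mean_bc_sq / s_cidr$mean_wc_sq,
      none = s_none$mean_bc_sq / s_none$mean_wc_sq,
      bc_shrink_cidr = s_cidr$mean_bc_sq / s_none$mean_bc_sq,
      bc_shrink_irm = s_irm$mean_bc_sq / s_none$mean_bc_sq)
  })
  expect_true(all(ratios["cidr", ] > ratios["none", ]))
  # row-mean imputation dilutes the between-cluster signal more
  expect_true(mean(ratios["bc_shrink_irm", ] < ratios["bc_shrink_cidr", ]) >= 0.9)
})

test_that("dissimilarity matrices round-trip through TSV", {
  set.seed(91)
  v <- small_logtpm_fixture(91, 20, 5)
  d <- cidr_dissimilarity(v, candidate_mask(v, rep(2, 5)),
                          dropout_model(1, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dissimilarity(d, path)
  back <- read_dissimilarity(path)
  expect_equal(back, unclass(d)[, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rownames(back), colnames(v))
})
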