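# Independent oracles used across the suite. These deliberately take the
# slow, literal route so they share no code path with the implementation.

# Literal pairwise-imputation distance: double loop over cell pairs,
# imputing feature-wise with impute_pair and taking the Euclidean norm.
naive_cidr_dist <- function(values, mask, model, use_step = TRUE) {
  n <- ncol(values)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      imp <- impute_pair(values[, i], values[, j], mask[, i], mask[, j],
                         model, use_step = use_step)
      d[i, j] <- d[j, i] <- sqrt(sum((imp$o_ki - imp$o_kj)^2))
    }
  }
  d
}

# Naive Ward agglomeration from first principles: repeatedly merge the
# pair of clusters with the smallest Ward cost
# |A||B|/(|A|+|B|) * ||centroid_A - centroid_B||^2, ties toward the
# lowest pair index. Returns the label vector after each merge.
naive_ward_partitions <- function(coords) {
  n <- nrow(coords)
  labels <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  out <- list()
  while (length(members) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        a <- coords[members[[i]], , drop = FALSE]
        b <- coords[members[[j]], , drop = FALSE]
        cost <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
          sum((colMeans(a) - colMeans(b))^2)
        if (cost < best[1]) best <- c(cost, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
    lab <- integer(n)
    for (g in seq_along(members)) lab[members[[g]]] <- g
    out[[length(out) + 1]] <- lab
  }
  out
}

# Brute-force adjusted Rand index by classifying every item pair as
# together/apart in each partition, then applying the pair-count form.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# A small logTPM-like fixture: two groups of cells with a block of
# differential features, plus dropout-style zeros.
small_logtpm_fixture <- function(seed = 42, n_feat = 30, n_cells = 8) {
  set.seed(seed)
  v <- matrix(stats::runif(n_feat * n_cells, 2, 10), n_feat, n_cells)
  v[1:10, 1:(n_cells / 2)] <- v[1:10, 1:(n_cells / 2)] + 4
  drop <- matrix(stats::runif(n_feat * n_cells) < 0.3, n_feat, n_cells)
  v[drop] <- 0
  dimnames(v) <- list(paste0("f", 1:n_feat), paste0("c", 1:n_cells))
  v
}
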