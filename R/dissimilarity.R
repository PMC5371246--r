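# CIDR dissimilarity by pair-local (implicit) imputation.
#
# For a pair of cells and a feature where exactly one value is a dropout
# candidate, the candidate is replaced by a weighted mean of the two values,
# with weight P(expressed value) under the logistic variant or its step
# simplification W under the default variant. Candidate-candidate pairs
# contribute zero; imputed values are never written back, so the imputation
# is implicit. The resulting squared distance admits a closed form
#
#   d2(i,j) = sum_k (v_ki - v_kj)^2 [ A_ki A_kj + B_ki A_kj q_kj
#                                     + A_ki q_ki B_kj ]
#
# with A the expressed indicator, B = 1 - A, and q = (1 - P(v))^2
# (logistic) or 1{v >= u*} (step), which is evaluated with a handful of
# feature-contracting cross-products instead of an explicit pair loop.

#' Pairwise implicit imputation for one feature
#'
#' Vectorized over features. When neither value is a dropout candidate both
#' are returned unchanged; when both are candidates both become zero; when
#' exactly one is a candidate it is replaced by the weighted mean
#' `w * expressed + (1 - w) * candidate` where `w` is the step weight
#' `W(expressed)` (default) or the fitted probability `P(expressed)`.
#'
#' @param o_ki,o_kj Observed values in cells i and j.
#' @param cand_i,cand_j Logical dropout-candidate flags.
#' @param model A [dropout_model()].
#' @param use_step Use the step simplification (default) rather than the
#'   full logistic weight.
#' @return A list with imputed vectors `o_ki` and `o_kj`.
#' @export
impute_pair <- function(o_ki, o_kj, cand_i, cand_j, model, use_step = TRUE) {
  n <- length(o_ki)
  stopifnot(length(o_kj) == n, length(cand_i) == n, length(cand_j) == n)
  wfun <- if (use_step) function(u) impute_weight(model, u)
          else function(u) predict(model, u)
  oi <- o_ki
  oj <- o_kj
  both <- cand_i & cand_j
  oi[both] <- 0
  oj[both] <- 0
  ionly <- cand_i & !cand_j
  if (any(ionly)) {
    w <- wfun(o_kj[ionly])
    oi[ionly] <- w * o_kj[ionly] + (1 - w) * o_ki[ionly]
  }
  jonly <- cand_j & !cand_i
  if (any(jonly)) {
    w <- wfun(o_ki[jonly])
    oj[jonly] <- w * o_ki[jonly] + (1 - w) * o_kj[jonly]
  }
  list(o_ki = oi, o_kj = oj)
}

#' CIDR dissimilarity matrix
#'
#' Computes, for every pair of cells, the Euclidean distance between the
#' pairwise-imputed expression profiles. Variants: `"step"` (default)
#' uses the step weighting function, `"logistic"` the full fitted
#' probability, `"none"` skips imputation entirely (plain Euclidean
#' distance on the logTPM values).
#'
#' @param values logTPM matrix (features x cells).
#' @param mask Candidate mask from [candidate_mask()].
#' @param model A fitted [dropout_model()]; ignored for `variant = "none"`.
#' @param variant `"step"`, `"logistic"` or `"none"`.
#' @return Symmetric cells x cells matrix of dissimilarities (unsquared),
#'   zero diagonal, with attribute `variant`. The triangle inequality is
#'   not guaranteed.
#' @export
cidr_dissimilarity <- function(values, mask, model = NULL,
                               variant = c("step", "logistic", "none")) {
  variant <- match.arg(variant)
  v <- unclass(values)
  if (variant == "none") {
    d <- as.matrix(stats::dist(t(v)))
  } else {
    if (is.null(model)) stop("a dropout model is required for this variant")
    stopifnot(all(dim(mask) == dim(v)))
    q <- if (variant == "step") {
      (v >= model$u_star) + 0
    } else {
      (1 - predict(model, v))^2
    }
    a <- (!mask) + 0           # expressed indicator
    av <- a * v
    av2 <- av * v
    p1 <- crossprod(av)
    p2 <- crossprod(a, av2)
    g <- a * q
    rm(q)
    gv <- g * v
    gv2 <- gv * v
    bv <- v - av
    bv2 <- v * v - av2
    rm(av, av2)
    t2 <- crossprod(bv2, g) - 2 * crossprod(bv, gv) + crossprod(1 - a, gv2)
    d2 <- t(p2) - 2 * p1 + p2 + t2 + t(t2)
    d2 <- (d2 + t(d2)) / 2     # enforce exact symmetry
    d2[d2 < 0] <- 0
    diag(d2) <- 0
    d <- sqrt(d2)
  }
  dimnames(d) <- list(colnames(values), colnames(values))
  attr(d, "variant") <- variant
  d
}

#' Row-mean imputation baseline dissimilarity
#'
#' Every dropout candidate is replaced (globally, not pairwise) by the mean
#' of its feature's expressed entries; Euclidean distances are then taken.
#' Features with no expressed entries have their candidates set to zero.
#'
#' @inheritParams cidr_dissimilarity
#' @return Symmetric dissimilarity matrix, attribute `variant = "irm"`.
#' @export
irm_dissimilarity <- function(values, mask) {
  v <- unclass(values)
  stopifnot(all(dim(mask) == dim(v)))
  n_expr <- rowSums(!mask)
  rmean <- ifelse(n_expr > 0, rowSums(v * !mask) / pmax(n_expr, 1), 0)
  if (any(n_expr == 0 & rowSums(mask) > 0))
    message(sum(n_expr == 0), " feature(s) with no expressed entries; ",
            "their candidates imputed to 0")
  imp <- v
  idx <- which(mask)
  imp[idx] <- rmean[((idx - 1L) %% nrow(v)) + 1L]
  d <- as.matrix(stats::dist(t(imp)))
  dimnames(d) <- list(colnames(values), colnames(values))
  attr(d, "variant") <- "irm"
  d
}

#' Write a dissimilarity matrix as TSV
#'
#' @param d Square dissimilarity matrix with cell identifiers.
#' @param path Output path.
#' @export
write_dissimilarity <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Read a dissimilarity matrix from TSV
#'
#' Loads a square matrix written by [write_dissimilarity()], e.g. to run
#' the embedding and clustering stages without recomputing distances.
#'
#' @param path Path to the TSV file.
#' @return Symmetric numeric matrix with cell identifiers.
#' @export
read_dissimilarity <- function(path) {
  d <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  d
}
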