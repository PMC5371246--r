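# Principal coordinate analysis (classical multidimensional scaling) of the
# CIDR dissimilarity matrix, with an optional Cailliez additive-constant
# correction and an eigenvalue-gap rule for choosing how many coordinates
# to carry into clustering.

#' Principal coordinate analysis
#'
#' Classical scaling: the squared dissimilarities are double-centred and
#' eigendecomposed; coordinates are eigenvectors scaled by the square roots
#' of their (positive) eigenvalues. Because a CIDR dissimilarity need not
#' satisfy the triangle inequality, some eigenvalues may be negative; they
#' carry no coordinates and are discarded when variation proportions are
#' computed.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param squared Set `TRUE` if `d` already holds squared dissimilarities.
#' @return Object of class `"cidr_pcoa"`: `eigenvalues` (all, descending),
#'   `coordinates` (cells x positive-eigenvalue axes), `variation`
#'   (proportions over positive eigenvalues).
#' @export
cidr_pcoa <- function(d, squared = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("dissimilarity matrix must be square and symmetric")
  if (squared) d <- sqrt(pmax(d, 0))
  n <- nrow(d)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE)
  )
  ev <- fit$eig
  tol <- 1e-10 * max(abs(ev), 1e-300)
  pos <- which(ev > tol)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PC", seq_along(pos))
  structure(
    list(eigenvalues = ev,
         coordinates = coords,
         variation = ev[pos] / sum(ev[pos]),
         n_cells = n),
    class = "cidr_pcoa"
  )
}

#' @export
print.cidr_pcoa <- function(x, ...) {
  npos <- ncol(x$coordinates)
  cat(sprintf("PCoA of %d cells: %d positive eigenvalues (of %d)\n",
              x$n_cells, npos, length(x$eigenvalues)))
  k <- min(5L, npos)
  cat("  variation explained by first axes:",
      paste(sprintf("%.1f%%", 100 * x$variation[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Cailliez additive-constant correction
#'
#' Finds the smallest constant `c` such that adding it to all off-diagonal
#' dissimilarities makes the matrix Euclidean-embeddable; the corrected
#' matrix has no negative PCoA eigenvalues. The constant is the largest
#' eigenvalue of the standard companion eigenproblem for the additive
#' constant, as computed by [stats::cmdscale()] with `add = TRUE`.
#'
#' @param d Symmetric dissimilarity matrix.
#' @return Corrected matrix with attribute `cailliez_constant`.
#' @export
cailliez_correct <- function(d) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = 1L, eig = TRUE, add = TRUE)
  )
  ac <- max(fit$ac, 0)
  out <- d + ac
  diag(out) <- 0
  attr(out, "cailliez_constant") <- ac
  out
}

#' Eigenvalue-gap grouping rule
#'
#' Shared machinery for choosing the number of principal coordinates and,
#' on a transformed curve, the number of clusters. Walking a descending
#' sequence, a new group opens whenever a consecutive difference exceeds
#' `cutoff_fraction` times the largest consecutive difference; as soon as
#' the current group's size exceeds `group_size_limit`, the total size of
#' all previous groups is returned. Returns `NA` when the walk completes
#' without the limit being exceeded.
#'
#' @param values Numeric vector, descending.
#' @param cutoff_fraction Fraction of the largest gap that opens a group.
#' @param group_size_limit Group size above which the rule fires.
#' @return Integer count, or `NA` if the rule never fires.
#' @keywords internal
gap_group_count <- function(values, cutoff_fraction, group_size_limit) {
  n <- length(values)
  if (n < 2L) return(NA_integer_)
  gaps <- -diff(values)
  cutoff <- cutoff_fraction * max(gaps)
  if (!is.finite(cutoff) || cutoff <= 0) return(NA_integer_)
  before <- 0L   # total size of completed groups
  size <- 1L     # size of the current group
  for (i in seq_len(n - 1L)) {
    if (gaps[i] > cutoff) {
      before <- before + size
      size <- 1L
    } else {
      size <- size + 1L
    }
    if (size > group_size_limit) return(before)
  }
  NA_integer_
}

#' Choose the number of principal coordinates
#'
#' A scree-style rule on the positive eigenvalues: eigenvalues are grouped
#' by their consecutive differences (see [gap_group_count()]); when the
#' trailing flat group grows past `group_size_limit`, the number of
#' eigenvalues in the preceding groups is returned. If the rule never
#' fires (no dominant gap structure), the bounded default `fallback` is
#' used and a message is emitted. The result is at least 1 and at most the
#' number of positive eigenvalues.
#'
#' @param eigenvalues Descending eigenvalues (negatives are ignored).
#' @param cutoff_fraction Fraction of the largest consecutive difference
#'   that starts a new group (default 0.1).
#' @param group_size_limit Maximum group size before the rule fires
#'   (default 2).
#' @param fallback Number of coordinates when the rule never fires
#'   (default 4).
#' @return Integer number of principal coordinates.
#' @export
select_n_pc <- function(eigenvalues, cutoff_fraction = 0.1,
                        group_size_limit = 2, fallback = 4) {
  ev <- sort(eigenvalues[eigenvalues > 0], decreasing = TRUE)
  # fewer than three eigenvalues carry no grouping evidence: minimum of 1
  if (length(ev) < 3L) return(1L)
  n <- gap_group_count(ev, cutoff_fraction, group_size_limit)
  if (is.na(n)) {
    message("no dominant eigenvalue gap; using the default of ",
            fallback, " principal coordinates")
    n <- fallback
  }
  max(1L, min(as.integer(n), length(ev)))
}

#' Export the variation-proportion curve
#'
#' Writes axis index, eigenvalue and proportion of variation as TSV.
#'
#' @param p A `"cidr_pcoa"` object.
#' @param path Output path.
#' @export
write_variation <- function(p, path) {
  pos <- seq_along(p$variation)
  utils::write.table(
    data.frame(axis = pos,
               eigenvalue = p$eigenvalues[pos],
               variation = p$variation),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
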