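# Hierarchical clustering on the leading principal coordinates, with the
# number of clusters chosen from the Calinski-Harabasz curve.

#' Ward hierarchical clustering
#'
#' Agglomerative clustering under Ward's minimum-variance criterion in the
#' variant that takes unsquared Euclidean distances and squares them
#' internally (`ward.D2`), cut at `k` groups. Given identical coordinates
#' the result is deterministic; merge ties break toward the lowest pair
#' index.
#'
#' @param coords Numeric matrix, cells x coordinates.
#' @param k Number of clusters, at most the number of cells.
#' @return Integer cluster labels per cell.
#' @export
ward_cluster <- function(coords, k) {
  coords <- as.matrix(coords)
  if (k > nrow(coords)) stop("k exceeds the number of cells")
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Calinski-Harabasz index
#'
#' `CH = [trace(B)/(k-1)] / [trace(W)/(n-k)]` where `B` and `W` are the
#' between- and within-cluster scatter matrices around the cluster
#' centroids. A degenerate partition with zero within-cluster scatter
#' returns `Inf`.
#'
#' @param coords Numeric matrix, cells x coordinates.
#' @param labels Cluster labels (>= 2 non-empty clusters).
#' @return The index value.
#' @export
calinski_harabasz <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.factor(labels)
  n <- nrow(coords)
  k <- nlevels(labels)
  if (k < 2L) stop("need at least two clusters")
  grand <- colMeans(coords)
  centroids <- apply(coords, 2L, function(col) tapply(col, labels, mean))
  centroids <- matrix(centroids, nrow = k)
  sizes <- as.numeric(table(labels))
  trB <- sum(sizes * rowSums(sweep(centroids, 2L, grand)^2))
  trW <- sum((coords - centroids[as.integer(labels), , drop = FALSE])^2)
  if (trW <= 0) {
    message("zero within-cluster scatter; Calinski-Harabasz index is infinite")
    return(Inf)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

#' Choose the number of clusters
#'
#' Computes the Calinski-Harabasz index for `k = 2..k_max` under Ward
#' clustering and examines the second derivative (central second
#' differences) of the curve: the chosen `k` is the sharpest concave bend,
#' i.e. the candidate with the most negative second difference, ties
#' breaking toward smaller `k`. A curve with no pronounced structure
#' (relative range of the index below 10% of its mean, or no concave
#' bend) yields the minimum of 2 clusters with a warning.
#'
#' @param coords Cells x coordinates matrix.
#' @param k_max Largest candidate number of clusters
#'   (default `min(10, cells - 1)`).
#' @param flat_fraction Relative range of the index below which the curve
#'   is declared structureless (default 0.1).
#' @return Integer `k` with attribute `ch_curve` (named index values for
#'   `k = 2..k_max`).
#' @export
select_n_clusters <- function(coords, k_max = NULL, flat_fraction = 0.1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(k_max)) k_max <- min(10L, n - 1L)
  if (k_max < 3L) stop("k_max must be at least 3")
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  ks <- 2:k_max
  ch <- vapply(ks, function(k)
    calinski_harabasz(coords, stats::cutree(hc, k = k)), numeric(1))
  names(ch) <- ks
  finite <- is.finite(ch)
  k <- if (!any(finite) ||
           diff(range(ch[finite])) < flat_fraction * mean(ch[finite])) {
    warning("Calinski-Harabasz curve is flat; defaulting to 2 clusters")
    2L
  } else {
    ch_for_diff <- ch
    ch_for_diff[!finite] <- max(ch[finite])
    s <- diff(ch_for_diff, differences = 2)   # second difference at k = 3..k_max-1
    names(s) <- ks[-c(1L, length(ks))]
    if (min(s) >= 0) {
      warning("no concave bend in the Calinski-Harabasz curve; ",
              "defaulting to 2 clusters")
      2L
    } else {
      as.integer(names(s)[which.min(s)])
    }
  }
  attr(k, "ch_curve") <- ch
  k
}

#' Cluster cells on principal coordinates
#'
#' Runs Ward clustering on the first `n_pc` coordinates of a PCoA result,
#' with the number of clusters chosen by [select_n_clusters()] unless
#' overridden.
#'
#' @param pcoa A `"cidr_pcoa"` object.
#' @param n_pc Number of leading coordinates to use.
#' @param n_cluster Optional user override of the number of clusters.
#' @param k_max,flat_fraction Passed to [select_n_clusters()].
#' @return Object of class `"cidr_clusters"`: `labels`, `k`, `ch_curve`,
#'   `n_pc`, `k_user_override`.
#' @export
cluster_cells <- function(pcoa, n_pc, n_cluster = NULL, k_max = NULL,
                          flat_fraction = 0.1) {
  coords <- pcoa$coordinates[, seq_len(min(n_pc, ncol(pcoa$coordinates))),
                             drop = FALSE]
  ch_curve <- NULL
  if (is.null(n_cluster)) {
    k <- select_n_clusters(coords, k_max = k_max,
                           flat_fraction = flat_fraction)
    ch_curve <- attr(k, "ch_curve")
    k <- as.integer(k)
  } else {
    k <- as.integer(n_cluster)
  }
  labels <- ward_cluster(coords, k)
  structure(
    list(labels = labels, k = k, ch_curve = ch_curve, n_pc = ncol(coords),
         k_user_override = n_cluster),
    class = "cidr_clusters"
  )
}

#' @export
print.cidr_clusters <- function(x, ...) {
  cat(sprintf("Ward clustering on %d principal coordinates: %d clusters%s\n",
              x$n_pc, x$k,
              if (!is.null(x$k_user_override)) " (user override)" else ""))
  print(table(cluster = x$labels))
  invisible(x)
}
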