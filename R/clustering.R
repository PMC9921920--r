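#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion.
#' The default dialect is \code{ward.D2}: the criterion operates on
#' squared Euclidean distances and merge heights are reported on the
#' distance scale, which is the correct Ward objective for Euclidean
#' input. The \code{ward.D} dialect (criterion applied to the distances
#' as given) is available as a switch.
#'
#' @param d A \code{dist} object (see \code{euclidean_distances()}),
#'   n >= 2, no missing entries.
#' @param dialect \code{"ward.D2"} (default) or \code{"ward.D"}.
#' @return An \code{hclust} tree with leaf labels taken from \code{d}.
#' @export
ward_linkage <- function(d, dialect = c("ward.D2", "ward.D")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(d, "dist"))
  if (attr(d, "Size") < 2) stop("at least 2 objects are required")
  if (anyNA(d)) stop("distance matrix contains missing values")
  stats::hclust(d, method = dialect)
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the merge height of the lowest cluster containing both
#' leaves -- an ultrametric distance by construction.
#'
#' @param tree An \code{hclust} object.
#' @return A \code{dist} object with the tree's labels.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  stats::cophenetic(tree)
}

#' Cut a dendrogram into k groups
#'
#' Removes the k - 1 highest merges; cluster ids are numbered by first
#' appearance in the original object order, so they are stable under
#' branch rotations.
#'
#' @param tree An \code{hclust} object over n leaves.
#' @param k Number of groups, 1 <= k <= n.
#' @return Integer vector of cluster labels named by leaf label.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  stats::cutree(tree, k = k)
}

#' k-means partitioning with k-means++ seeding
#'
#' Lloyd iterations from k-means++ starting centers, best of
#' \code{n_restarts} runs by within-cluster sum of squares. The mean
#' silhouette width (Euclidean) is attached for model selection.
#'
#' @param m Numeric matrix (observations x variables), rows >= k.
#' @param k Number of clusters (>= 1).
#' @param n_restarts Independent seeded restarts (default 25).
#' @param seed Integer seed.
#' @param max_iter Lloyd iteration cap per run (default 300).
#' @return Object of class \code{cluster_solution}: list with \code{k},
#'   \code{labels}, \code{centers}, \code{inertia} and \code{silhouette}
#'   (NA when k = 1 or k = n).
#' @export
kmeans_cluster <- function(m, k, n_restarts = 25, seed = 1, max_iter = 300) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (k < 1) stop("k must be at least 1")
  if (n < k) stop("need at least k = ", k, " rows, got ", n)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(m, k)
    fit <- suppressWarnings(
      stats::kmeans(m, centers = centers, iter.max = max_iter,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  sil <- NA_real_
  if (k > 1 && k < n) {
    sw <- cluster::silhouette(best$cluster, stats::dist(m))
    sil <- mean(sw[, "sil_width"])
  }
  structure(list(k = k, labels = unname(best$cluster),
                 centers = best$centers,
                 inertia = best$tot.withinss, silhouette = sil),
            class = "cluster_solution")
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1) {
    d2 <- rowSums((m - matrix(m[idx[1], ], n, ncol(m), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums((m - matrix(m[idx[j], ], n, ncol(m),
                                         byrow = TRUE))^2))
    }
  }
  m[idx, , drop = FALSE] + 0  # drop names; jitter-free copy
}

#' Choose the number of clusters by silhouette, with the elbow curve
#'
#' Runs \code{kmeans_cluster} over \code{k_range} and recommends the
#' silhouette-maximizing k (ties broken toward smaller k). The
#' within-cluster sum-of-squares (elbow) curve is returned for the report.
#'
#' @param m Numeric matrix (observations x variables).
#' @param k_range Candidate k values, a subset of [2, nrow(m) - 1].
#' @param n_restarts,seed Passed to \code{kmeans_cluster}.
#' @return List with \code{k} (recommended), \code{silhouette_curve},
#'   \code{wss_curve} (both named by k) and \code{solutions}.
#' @export
choose_k <- function(m, k_range = 2:6, n_restarts = 25, seed = 1) {
  m <- as.matrix(m)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("empty candidate range for k")
  if (min(k_range) < 2 || max(k_range) > nrow(m) - 1) {
    stop("k_range must lie within [2, ", nrow(m) - 1, "]")
  }
  sols <- lapply(seq_along(k_range), function(i)
    kmeans_cluster(m, k_range[i], n_restarts = n_restarts, seed = seed + i))
  sil <- vapply(sols, `[[`, numeric(1), "silhouette")
  wss <- vapply(sols, `[[`, numeric(1), "inertia")
  names(sil) <- names(wss) <- k_range
  list(k = k_range[which.max(sil)],  # which.max: first max -> smallest k
       silhouette_curve = sil, wss_curve = wss, solutions = sols)
}

#' Two-way clustering of a feature matrix
#'
#' Rows (participants) and columns (items) are clustered independently
#' with Ward linkage on Euclidean distances after column-wise min-max
#' scaling, giving the ordering pair that underlies a clustered heatmap.
#'
#' @param m Numeric matrix, no missing values.
#' @param scale Apply column-wise min-max scaling first (default TRUE).
#' @return Object of class \code{two_way_ordering}: list with
#'   \code{row_tree}, \code{col_tree} (hclust), \code{row_order},
#'   \code{col_order} (leaf-order permutations) and \code{scaled_matrix}.
#' @export
two_way_cluster <- function(m, scale = TRUE) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("two-way clustering requires complete data")
  sm <- m
  if (scale && nrow(sm) > 1) {
    for (j in seq_len(ncol(sm))) {
      sm[, j] <- minmax_scale(sm[, j], name = colnames(sm)[j] %||%
                                as.character(j))
    }
  }
  if (nrow(sm) < 2 || ncol(sm) < 2) {
    ro <- seq_len(nrow(sm)); co <- seq_len(ncol(sm))
    return(structure(list(row_tree = NULL, col_tree = NULL,
                          row_order = ro, col_order = co,
                          scaled_matrix = sm), class = "two_way_ordering"))
  }
  row_tree <- ward_linkage(euclidean_distances(sm, "rows"))
  col_tree <- ward_linkage(euclidean_distances(sm, "columns"))
  structure(list(row_tree = row_tree, col_tree = col_tree,
                 row_order = row_tree$order, col_order = col_tree$order,
                 scaled_matrix = sm), class = "two_way_ordering")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("k-means solution: k =", x$k,
      "| inertia =", format(x$inertia, digits = 6),
      "| mean silhouette =", format(x$silhouette, digits = 4), "\n")
  invisible(x)
}

#' @export
print.two_way_ordering <- function(x, ...) {
  cat("Two-way clustering:", nrow(x$scaled_matrix), "rows x",
      ncol(x$scaled_matrix), "columns\n")
  invisible(x)
}
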