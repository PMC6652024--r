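#' Approximate the number of clusters by iterative subsampling
#'
#' Estimates how many clusters a one-dimensional value set contains without
#' clustering the full set: `n_subsamples` seeded subsamples of at most
#' `subsample_size` points are each fitted with univariate Gaussian mixtures
#' (equal- and unequal-variance) over `1..k_max` components, the component
#' count with the best BIC is recorded, and the rounded mean of the
#' per-subsample estimates is returned. When the input is no larger than one
#' subsample a single fit on the full set is used.
#'
#' The estimate is scale-equivariant (BIC differences are unchanged by affine
#' transforms of the values) and deterministic given `seed`.
#'
#' @param values Numeric vector, length >= 2.
#' @param k_max Upper bound for the component search (>= 2).
#' @param seed Integer seed driving the subsample draws.
#' @param subsample_size Points per subsample (default 500).
#' @param n_subsamples Number of subsamples when the input exceeds
#'   `subsample_size` (default 10).
#'
#' @return A single integer `k`, `1 <= k <= min(k_max, #distinct values)`.
#'   All-identical input returns 1.
#' @export
approximate_k <- function(values, k_max = 10L, seed = 1L,
                          subsample_size = 500L, n_subsamples = 10L) {
  values <- as.numeric(values)
  n <- length(values)
  n_distinct <- length(unique(values))
  if (n_distinct < 2L) return(1L)
  if (k_max < 2L) stop_config("approximate_k: k_max must be >= 2")
  m <- min(as.integer(subsample_size), n)
  n_rep <- if (m >= n) 1L else as.integer(n_subsamples)
  ks <- with_seed(seed, vapply(seq_len(n_rep), function(r) {
    sub <- if (m >= n) values else values[sample.int(n, m)]
    g_max <- min(k_max, length(unique(sub)))
    if (g_max < 2L) return(1)
    bic <- tryCatch(
      mclust::mclustBIC(sub, G = seq_len(g_max), modelNames = c("E", "V"),
                        verbose = FALSE),
      error = function(e) NULL
    )
    if (is.null(bic) || all(is.na(bic))) return(1)
    best <- which(bic == max(bic, na.rm = TRUE), arr.ind = TRUE)[1, ]
    as.numeric(rownames(bic)[best[1]])
  }, numeric(1)))
  k <- as.integer(round(mean(ks)))
  max(1L, min(k, n_distinct, as.integer(k_max)))
}

#' Initial centroids from a hierarchical-clustering cut
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance) is cut at
#' `k` groups and each group's mean becomes one centroid. These centroids
#' replace random initialization in the hybrid hierarchical K-means scheme,
#' making the downstream K-means run deterministic.
#'
#' @param values Numeric vector.
#' @param k Number of groups; reduced with a warning if it exceeds the
#'   number of distinct values.
#' @return Numeric vector of `k` centroids, sorted ascending.
#' @examples
#' hierarchical_centroids(c(0, 1, 10, 11), 2)  # 0.5, 10.5
#' @export
hierarchical_centroids <- function(values, k) {
  values <- as.numeric(values)
  n_distinct <- length(unique(values))
  k <- as.integer(k)
  if (k > n_distinct) {
    warning(sprintf("k = %d exceeds %d distinct values; reducing", k, n_distinct))
    k <- n_distinct
  }
  if (k <= 1L) return(mean(values))
  tree <- stats::hclust(stats::dist(values), method = "ward.D2")
  membership <- stats::cutree(tree, k = k)
  cen <- vapply(seq_len(k), function(j) mean(values[membership == j]), numeric(1))
  sort(cen)
}

new_cluster_model <- function(values, centroids, assignments,
                              iterations, distortion_trace) {
  populations <- tabulate(assignments, nbins = length(centroids))
  distortion <- sum((values - centroids[assignments])^2)
  structure(
    list(k = length(centroids),
         centroids = centroids,
         assignments = as.integer(assignments),
         populations = as.integer(populations),
         distortion = distortion,
         iterations = as.integer(iterations),
         distortion_trace = distortion_trace),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, n = %d, distortion = %g (%d iterations)\n",
              x$k, length(x$assignments), x$distortion, x$iterations))
  cat("  populations:", x$populations, "\n")
  invisible(x)
}

#' K-means refinement (Lloyd iterations) from given centroids
#'
#' Iterates the two K-means steps — assign each point to its nearest centroid
#' (squared Euclidean distance, ties broken toward the lowest cluster index),
#' then move each centroid to the mean of its points — until the assignments
#' stop changing or `max_iter` is reached. Centroids that lose all points are
#' dropped and `k` is reduced. The within-cluster sum of squares recorded
#' after each assignment step is non-increasing; the trace is returned so the
#' property can be audited.
#'
#' @param values Numeric vector.
#' @param centroids Numeric vector of initial centroids.
#' @param max_iter Iteration cap (default 100).
#'
#' @return A `cluster_model`: list with `k`, `centroids`, `assignments`
#'   (1-based), `populations`, `distortion` (within-cluster sum of squares),
#'   `iterations`, and `distortion_trace`.
#' @examples
#' m <- kmeans_refine(c(0, 1, 10, 11), c(0.5, 10.5))
#' m$assignments  # 1 1 2 2
#' m$distortion   # 1.0
#' @export
kmeans_refine <- function(values, centroids, max_iter = 100L) {
  values <- as.numeric(values)
  cen <- as.numeric(centroids)
  if (length(cen) < 1L) stop_validation("kmeans_refine: need at least one centroid")
  if (length(values) < length(cen)) {
    stop_validation("kmeans_refine: more centroids than points")
  }
  trace <- numeric(0)
  assignments <- integer(0)
  iterations <- 0L
  repeat {
    dmat <- abs(outer(values, cen, "-"))
    new_assign <- max.col(-dmat, ties.method = "first")
    trace <- c(trace, sum((values - cen[new_assign])^2))
    # drop centroids left without points, renumbering compactly
    keep <- which(tabulate(new_assign, nbins = length(cen)) > 0L)
    if (length(keep) < length(cen)) {
      cen <- cen[keep]
      new_assign <- match(new_assign, keep)
    }
    if (identical(new_assign, assignments) || iterations >= max_iter) {
      assignments <- new_assign
      cen <- vapply(seq_along(cen), function(j) mean(values[assignments == j]),
                    numeric(1))
      break
    }
    assignments <- new_assign
    cen <- vapply(seq_along(cen), function(j) mean(values[assignments == j]),
                  numeric(1))
    iterations <- iterations + 1L
  }
  new_cluster_model(values, cen, assignments, iterations, trace)
}

#' Hybrid hierarchical K-means clustering
#'
#' Runs [hierarchical_centroids()] to obtain deterministic initial centers,
#' then [kmeans_refine()] to convergence. For inputs larger than
#' `hclust_cap` points the quadratic-memory hierarchical step runs on a
#' seeded subsample of `hclust_cap` points; all points then enter the
#' K-means refinement, which only ever lowers the within-cluster sum of
#' squares relative to the initial partition.
#'
#' @param values Numeric vector.
#' @param k Number of clusters requested.
#' @param seed Seed for the initialization subsample (only drawn when
#'   `length(values) > hclust_cap`).
#' @param hclust_cap Largest input clustered hierarchically in full
#'   (default 2000).
#' @param max_iter Passed to [kmeans_refine()].
#' @return A `cluster_model`.
#' @examples
#' hkmeans(c(0, 1, 10, 11), 2)$populations  # 2 2
#' @export
hkmeans <- function(values, k, seed = 1L, hclust_cap = 2000L, max_iter = 100L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n > hclust_cap) {
    idx <- with_seed(seed, sample.int(n, hclust_cap))
    cen <- hierarchical_centroids(values[idx], k)
  } else {
    cen <- hierarchical_centroids(values, k)
  }
  kmeans_refine(values, cen, max_iter = max_iter)
}

#' Cluster census: population of every cluster
#'
#' @param model A `cluster_model`.
#' @return Data frame with columns `cluster_index`, `population`; populations
#'   sum to the number of clustered points.
#' @export
cluster_census <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  data.frame(cluster_index = seq_len(model$k), population = model$populations)
}

#' Maximum cluster population flaggable as implausible
#'
#' Under sparsity ratio `alpha`, a cluster is implausible when its share of
#' the fold is at most `alpha`, i.e. its population is at most
#' `floor(alpha * fold_length)`. With the canonical coupling
#' `fold_length = 1/alpha` the threshold is exactly 1: only singleton
#' clusters are flagged.
#'
#' @param fold_length Number of points in the fold (>= 1).
#' @param alpha Sparsity ratio in (0, 1].
#' @return Non-negative integer threshold.
#' @examples
#' flag_threshold(10000, 1 / 10000)  # 1
#' flag_threshold(10000, 1 / 500)    # 20
#' @export
flag_threshold <- function(fold_length, alpha) {
  if (fold_length < 1) stop_validation("flag_threshold: fold_length must be >= 1")
  if (!(alpha > 0 && alpha <= 1)) {
    stop_validation("flag_threshold: alpha must lie in (0, 1]")
  }
  # epsilon guards against 0.999... artefacts of alpha stored as 1/n
  as.integer(floor(alpha * fold_length + 1e-9))
}

#' Points belonging to sparse clusters
#'
#' @param model A `cluster_model`.
#' @param threshold Maximum population of a flaggable cluster; 0 flags
#'   nothing.
#' @return Integer indices (into the clustered values) of all points whose
#'   cluster population is `<= threshold`.
#' @export
flag_sparse <- function(model, threshold) {
  stopifnot(inherits(model, "cluster_model"))
  threshold <- as.integer(threshold)
  if (threshold < 0L) stop_validation("flag_sparse: threshold must be >= 0")
  if (threshold == 0L) return(integer(0))
  which(model$populations[model$assignments] <= threshold)
}
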