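#' The eight canonical sparsity ratios
#'
#' The evaluated grid of sparsity ratios, from most liberal (1/500) to most
#' stringent (1/10,000).
#'
#' @return Numeric vector of eight ratios, descending.
#' @export
default_alphas <- function() {
  1 / c(500, 1000, 2000, 3000, 4000, 5000, 6000, 10000)
}

#' Configuration for the fold-and-flag pipeline
#'
#' Bundles every tunable of the detector. The sparsity ratio `alpha` and the
#' fold size are coupled by default (`fold_size = round(1/alpha)`), so that a
#' cluster is flagged when its population is at most `alpha` of its fold —
#' with the default coupling, a single point. Both remain independently
#' settable because the flag rule is expressed as a population fraction.
#'
#' @param alpha Sparsity ratio in (0, 1]. Canonical values are
#'   [default_alphas()]; any ratio is permitted. Default 1/5000, the middle
#'   of the range recommended for large repositories.
#' @param fold_size Points per fold (>= 2); defaults to `round(1/alpha)`.
#' @param seed Integer seed for the shuffle and every stochastic sub-step.
#' @param k_max Cap for the cluster-number search (default 10).
#' @param transform `"scale_cube"` (center, scale to unit sample SD, cube —
#'   the default, emphasizing distribution tails) or `"none"`.
#' @param subsample_size,n_subsamples Passed to [approximate_k()].
#' @param hclust_cap Passed to [hkmeans()].
#' @param max_iter Passed to [kmeans_refine()].
#'
#' @return Object of class `flag_config`.
#' @export
flag_config <- function(alpha = 1 / 5000, fold_size = NULL, seed = 1L,
                        k_max = 10L, transform = c("scale_cube", "none"),
                        subsample_size = 500L, n_subsamples = 10L,
                        hclust_cap = 2000L, max_iter = 100L) {
  transform <- match.arg(transform)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1)) {
    stop_config("flag_config: alpha must be a single number in (0, 1]")
  }
  if (is.null(fold_size)) fold_size <- max(2L, as.integer(round(1 / alpha)))
  fold_size <- as.integer(fold_size)
  if (fold_size < 2L) stop_config("flag_config: fold_size must be >= 2")
  if (k_max < 2L) stop_config("flag_config: k_max must be >= 2")
  structure(
    list(alpha = alpha, fold_size = fold_size, seed = as.integer(seed),
         k_max = as.integer(k_max), transform = transform,
         subsample_size = as.integer(subsample_size),
         n_subsamples = as.integer(n_subsamples),
         hclust_cap = as.integer(hclust_cap),
         max_iter = as.integer(max_iter)),
    class = "flag_config"
  )
}

#' @export
print.flag_config <- function(x, ...) {
  cat(sprintf("<flag_config> alpha = 1/%g, fold_size = %d, seed = %d, k_max = %d, transform = %s\n",
              round(1 / x$alpha), x$fold_size, x$seed, x$k_max, x$transform))
  invisible(x)
}

#' Read a pipeline configuration from JSON
#'
#' Every field of [flag_config()] may appear in the JSON object; absent
#' fields take their defaults. Unknown fields are a configuration error.
#'
#' @param path Path to a JSON file.
#' @return A `flag_config`.
#' @export
read_flag_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_config(sprintf(
                    "cannot parse config %s: %s", path, conditionMessage(e))))
  unknown <- setdiff(names(raw), names(formals(flag_config)))
  if (length(unknown)) {
    stop_config(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(flag_config, raw)
}

#' Shuffle an observation series
#'
#' Random permutation of the series to destroy any source ordering (by
#' patient, time or value) before fold partitioning, so folds are
#' exchangeable. Deterministic given `seed`.
#'
#' @param series An [observation_series()].
#' @param seed Integer seed.
#' @return The permuted `observation_series` (same multiset of
#'   value/row-id pairs).
#' @export
shuffle_observations <- function(series, seed) {
  stopifnot(inherits(series, "observation_series"))
  n <- length(series$values)
  if (n == 0L) stop_validation("shuffle_observations: empty series")
  perm <- with_seed(seed, sample.int(n))
  observation_series(series$values[perm], series$row_ids[perm],
                     series$concept_code, series$n_excluded)
}

#' Partition a (shuffled) series into folds
#'
#' Splits the series, in order, into consecutive folds of `fold_size` points;
#' the last fold holds whatever remains (1 to `fold_size` points). Folds are
#' disjoint and jointly exhaustive, and each is processed independently —
#' this is the unit of parallelism.
#'
#' @param series An [observation_series()] (normally already shuffled).
#' @param fold_size Points per fold (>= 2).
#' @return List of fold specs, each a list with `fold_index` (1-based),
#'   `idx` (positions in the series) and `row_ids`.
#' @export
partition_folds <- function(series, fold_size) {
  stopifnot(inherits(series, "observation_series"))
  fold_size <- as.integer(fold_size)
  if (fold_size < 2L) stop_config("partition_folds: fold_size must be >= 2")
  n <- length(series$values)
  if (n == 0L) return(list())
  grp <- ceiling(seq_len(n) / fold_size)
  lapply(seq_len(max(grp)), function(j) {
    idx <- which(grp == j)
    list(fold_index = j, idx = idx, row_ids = series$row_ids[idx])
  })
}

#' Center, scale and cube
#'
#' Standardizes values to zero mean and unit sample standard deviation, then
#' raises each to the third power. Cubing preserves sign and order but
#' stretches both tails, so tail points separate more readily into their own
#' clusters while the distribution body contracts. A zero-variance input
#' maps to all zeros.
#'
#' @param values Numeric vector.
#' @return Transformed numeric vector of the same length; strictly rank
#'   order preserving whenever the input has positive variance.
#' @examples
#' scale_and_cube(c(-1, 0, 1))  # fixed points: -1 0 1
#' @export
scale_and_cube <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) return(rep(0, length(values)))
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(0, length(values)))
  ((values - mean(values)) / s)^3
}

#' Cluster and flag a single fold
#'
#' The per-fold procedure: transform the values, approximate the cluster
#' number, cluster with [hkmeans()], take the cluster census, and flag every
#' point whose cluster population is at most `flag_threshold(n, alpha)`.
#' Flags refer to the original (untransformed) fold positions. A fold of
#' fewer than 2 points cannot be clustered; it is passed through unflagged
#' with a warning.
#'
#' @param values Numeric vector: the fold's observation values.
#' @param config A [flag_config()]; `config$seed` drives this fold's
#'   stochastic sub-steps.
#' @return List with `model` (a `cluster_model`), logical `flags`, and the
#'   integer `threshold` applied.
#' @export
run_fold <- function(values, config) {
  stopifnot(inherits(config, "flag_config"))
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) {
    warning("fold of fewer than 2 points: skipped (no flags)")
    model <- new_cluster_model(values, mean(values), rep(1L, n), 0L, numeric(0))
    return(list(model = model, flags = rep(FALSE, n), threshold = 0L))
  }
  work <- switch(config$transform,
                 scale_cube = scale_and_cube(values),
                 none = values)
  k <- approximate_k(work, k_max = config$k_max, seed = config$seed,
                     subsample_size = config$subsample_size,
                     n_subsamples = config$n_subsamples)
  model <- hkmeans(work, k, seed = config$seed,
                   hclust_cap = config$hclust_cap, max_iter = config$max_iter)
  threshold <- flag_threshold(n, config$alpha)
  flags <- rep(FALSE, n)
  flags[flag_sparse(model, threshold)] <- TRUE
  list(model = model, flags = flags, threshold = threshold)
}

#' Run the full detector on one observation series
#'
#' Shuffle, partition into folds, run [run_fold()] on every fold (each fold
#' gets a sub-seed derived from `config$seed` and its index, so folds are
#' independent and the result is identical whether folds run sequentially or
#' concurrently), and aggregate a flag report covering every input row
#' exactly once, in the original series order.
#'
#' @param series An [observation_series()].
#' @param config A [flag_config()].
#' @return A `flag_report` data frame with columns `row_id`, `value`,
#'   `flagged`, `fold_index`, `cluster_index`, `cluster_population`.
#' @examples
#' s <- observation_series(c(rnorm(98), 50, -50))
#' rep <- run_pipeline(s, flag_config(alpha = 1/50, fold_size = 100, seed = 7))
#' sum(rep$flagged)
#' @export
run_pipeline <- function(series, config) {
  stopifnot(inherits(series, "observation_series"), inherits(config, "flag_config"))
  if (length(series$values) == 0L) stop_validation("run_pipeline: empty series")
  shuffled <- shuffle_observations(series, config$seed)
  folds <- partition_folds(shuffled, config$fold_size)
  pieces <- lapply(folds, function(f) {
    sub_config <- config
    sub_config$seed <- fold_seed(config$seed, f$fold_index)
    res <- run_fold(shuffled$values[f$idx], sub_config)
    data.frame(
      row_id = f$row_ids,
      value = shuffled$values[f$idx],
      flagged = res$flags,
      fold_index = f$fold_index,
      cluster_index = res$model$assignments,
      cluster_population = res$model$populations[res$model$assignments],
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, pieces)
  report <- report[match(series$row_ids, report$row_id), , drop = FALSE]
  rownames(report) <- NULL
  report <- new_flag_report(report)
  attr(report, "concept_code") <- series$concept_code
  attr(report, "alpha") <- config$alpha
  report
}
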