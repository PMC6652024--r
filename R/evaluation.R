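#' Silver-standard implausibility labels
#'
#' Labels every value of a series against its silver-standard interval:
#' implausible (`TRUE`) iff the value is strictly below `low` or strictly
#' above `high`. The bounds themselves are plausible (closed interval).
#'
#' @param series An [observation_series()] or a numeric vector.
#' @param standard A [silver_standard()].
#' @return Logical vector, `TRUE` = implausible.
#' @examples
#' ts <- silver_standard("10839-9", 0, 20)
#' silver_labels(c(0.2, 20, 25), ts)  # FALSE FALSE TRUE
#' @export
silver_labels <- function(series, standard) {
  stopifnot(inherits(standard, "silver_standard"))
  values <- if (inherits(series, "observation_series")) series$values else as.numeric(series)
  values < standard$low | values > standard$high
}

#' Confusion-matrix evaluation of a flag vector
#'
#' Compares detector flags with silver-standard labels and reports the
#' counts plus sensitivity, specificity and fallout. Sensitivity is
#' undefined (`NA`) when there are no truly implausible rows — observation
#' types without positives are excluded from sensitivity summaries rather
#' than scored 0 or 1.
#'
#' @param labels Logical vector of ground-truth implausibility labels.
#' @param flags Logical vector of detector flags, same length.
#' @return Object of class `evaluation_result`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `fallout`.
#' @export
confusion <- function(labels, flags) {
  labels <- as.logical(labels); flags <- as.logical(flags)
  if (length(labels) != length(flags)) {
    stop_validation("confusion: labels and flags differ in length")
  }
  tp <- sum(labels & flags); fn <- sum(labels & !flags)
  fp <- sum(!labels & flags); tn <- sum(!labels & !flags)
  sensitivity <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sensitivity, specificity = specificity,
         fallout = if (is.na(specificity)) NA_real_ else 1 - specificity),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> tp %d fp %d tn %d fn %d | sens %s spec %s\n",
              x$tp, x$fp, x$tn, x$fn,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.4f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.4f", x$specificity))))
  invisible(x)
}

#' Paired false-positive comparison of two detectors
#'
#' Counts the false positives of two detectors on the truly plausible rows
#' and tests whether they false-positive at different rates, using an exact
#' two-sided binomial test on the discordant rows (rows where exactly one
#' detector fires), null proportion 1/2 — the exact McNemar construction.
#' With no discordant rows the p-value is 1.
#'
#' @param labels Logical ground-truth labels (`TRUE` = implausible).
#' @param flags_a,flags_b Logical flag vectors of the two detectors.
#' @return List with `fp_a`, `fp_b`, `p_value`.
#' @export
compare_false_positives <- function(labels, flags_a, flags_b) {
  labels <- as.logical(labels)
  if (length(flags_a) != length(labels) || length(flags_b) != length(labels)) {
    stop_validation("compare_false_positives: length mismatch")
  }
  plausible <- !labels
  fa <- flags_a & plausible
  fb <- flags_b & plausible
  n10 <- sum(fa & !fb)
  n01 <- sum(!fa & fb)
  p <- if (n10 + n01 == 0L) 1 else {
    stats::binom.test(n10, n10 + n01, p = 0.5)$p.value
  }
  list(fp_a = sum(fa), fp_b = sum(fb), p_value = p)
}

#' Evaluate the detector across a grid of sparsity ratios
#'
#' Runs the full pipeline once per `alpha` (fold size re-coupled to
#' `round(1/alpha)` unless the caller fixes `fold_size` in `config`) and
#' evaluates each run against the silver standard.
#'
#' @param series An [observation_series()].
#' @param standard A [silver_standard()] for the series' concept.
#' @param alphas Sparsity ratios to evaluate (default [default_alphas()]).
#' @param config Base [flag_config()]; its `alpha`/`fold_size` are
#'   overridden per grid point.
#' @param couple_fold_size If `TRUE` (default) set `fold_size = round(1/alpha)`
#'   at each grid point.
#' @return Data frame ordered by `alpha` descending with columns `alpha`,
#'   `fold_size`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `fallout`.
#' @export
sweep_alphas <- function(series, standard, alphas = default_alphas(),
                         config = flag_config(), couple_fold_size = TRUE) {
  if (length(alphas) == 0L) stop_config("sweep_alphas: alphas must be non-empty")
  alphas <- sort(as.numeric(alphas), decreasing = TRUE)
  labels <- silver_labels(series, standard)
  rows <- lapply(alphas, function(a) {
    cfg <- config
    cfg$alpha <- a
    if (couple_fold_size) cfg$fold_size <- max(2L, as.integer(round(1 / a)))
    rep_a <- run_pipeline(series, cfg)
    ev <- confusion(labels, rep_a$flagged)
    data.frame(alpha = a, fold_size = cfg$fold_size,
               tp = ev$tp, fp = ev$fp, tn = ev$tn, fn = ev$fn,
               sensitivity = ev$sensitivity, specificity = ev$specificity,
               fallout = ev$fallout)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
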