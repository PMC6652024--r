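#' Standard-deviation outlier flags
#'
#' The classical global rule: flag a value when it lies more than
#' `multiplier` sample standard deviations from the series mean. Mean and SD
#' are computed on the full series; a zero-variance series yields no flags.
#' The default multiplier of 6 is the best-performing SD cutoff among the
#' conventional baselines.
#'
#' @param values Numeric vector, length >= 2.
#' @param multiplier Positive cutoff in SD units (default 6).
#' @return Logical vector of flags.
#' @export
sd_flags <- function(values, multiplier = 6) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_validation("sd_flags: need at least 2 values")
  if (multiplier <= 0) stop_config("sd_flags: multiplier must be > 0")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > multiplier * s
}

#' Mahalanobis-distance outlier flags
#'
#' Flags a value when its Mahalanobis distance from the series mean exceeds
#' `critical` (strictly). In one dimension the distance reduces to
#' `|v - mean| / sd`, so this baseline differs from [sd_flags()] only in its
#' default cutoff: 3.717526, the square root of 13.82, the critical value
#' used by the best-performing distance baseline. Zero-variance series yield
#' no flags.
#'
#' @param values Numeric vector, length >= 2.
#' @param critical Positive critical distance (default 3.717526).
#' @return Logical vector of flags.
#' @export
mahalanobis_flags <- function(values, critical = 3.717526) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_validation("mahalanobis_flags: need at least 2 values")
  if (critical <= 0) stop_config("mahalanobis_flags: critical must be > 0")
  v <- stats::var(values)
  if (!is.finite(v) || v == 0) return(rep(FALSE, length(values)))
  d2 <- stats::mahalanobis(matrix(values, ncol = 1), center = mean(values), cov = v)
  sqrt(d2) > critical
}

#' Conventional anomaly detection dispatcher
#'
#' Runs one of the two conventional baselines with its configured cutoff.
#'
#' @param values Numeric vector.
#' @param method `"sd"` or `"mahalanobis"`.
#' @param sd_multiplier Cutoff for the SD method (default 6).
#' @param critical Cutoff for the Mahalanobis method (default 3.717526).
#' @return Logical vector of flags.
#' @export
cad_flags <- function(values, method = c("sd", "mahalanobis"),
                      sd_multiplier = 6, critical = 3.717526) {
  method <- match.arg(method)
  switch(method,
         sd = sd_flags(values, sd_multiplier),
         mahalanobis = mahalanobis_flags(values, critical))
}
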