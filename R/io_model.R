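#' Construct an observation series
#'
#' An observation series holds every recorded numeric value for one
#' observation type (one LOINC-style concept code), together with stable
#' per-row provenance identifiers. It is the unit of analysis: the detector
#' operates on one observation type at a time and never mixes concepts.
#'
#' @param values Numeric vector of finite observation values, in source order.
#' @param row_ids Character vector of unique provenance identifiers, same
#'   length as `values`. Defaults to `"r1"`, `"r2"`, ...
#' @param concept_code Identifier of the observation type (e.g. a LOINC code).
#' @param n_excluded Count of source rows dropped because their value was
#'   missing or non-numeric; retained for reporting.
#'
#' @return An object of class `observation_series`: a list with fields
#'   `concept_code`, `values`, `row_ids`, `n_excluded`.
#' @examples
#' observation_series(c(0.12, 0.31, 0.08), concept_code = "10839-9")
#' @export
observation_series <- function(values, row_ids = NULL,
                               concept_code = "unknown", n_excluded = 0L) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop_validation("observation_series: all values must be finite; filter first")
  }
  if (is.null(row_ids)) {
    row_ids <- if (length(values)) paste0("r", seq_along(values)) else character(0)
  }
  row_ids <- as.character(row_ids)
  if (length(row_ids) != length(values)) {
    stop_validation("observation_series: row_ids and values differ in length")
  }
  if (anyDuplicated(row_ids)) {
    stop_validation("observation_series: row_ids must be unique")
  }
  structure(
    list(concept_code = as.character(concept_code)[1],
         values = values, row_ids = row_ids,
         n_excluded = as.integer(n_excluded)),
    class = "observation_series"
  )
}

#' @export
length.observation_series <- function(x) length(x$values)

#' @export
print.observation_series <- function(x, ...) {
  cat(sprintf("<observation_series> %s: %d values (%d excluded)\n",
              x$concept_code, length(x$values), x$n_excluded))
  if (length(x$values)) {
    cat("  range:", format(range(x$values)), "\n")
  }
  invisible(x)
}

#' Read observation tables into per-concept series
#'
#' Reads a delimited text file of raw observations and splits it into one
#' [observation_series()] per distinct concept code, preserving file order.
#' Rows whose value does not parse as a finite number are excluded and
#' counted per concept rather than raising an error: clinical extracts
#' routinely carry textual results in numeric columns.
#'
#' Default column names follow the i2b2 `observation_fact` convention
#' (`concept_cd`, `nval_num`).
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param concept_col,value_col Names of the concept-code and numeric-value
#'   columns.
#' @param id_col Optional name of a column holding stable row identifiers;
#'   when `NULL`, file row numbers are used.
#' @param sep Field delimiter; `"auto"` (default) lets the reader infer it.
#'
#' @return Named list mapping concept code to `observation_series`.
#' @export
read_observations <- function(path, concept_col = "concept_cd",
                              value_col = "nval_num", id_col = NULL,
                              sep = "auto") {
  if (!file.exists(path)) stop_io(sprintf("observation file not found: %s", path))
  dt <- tryCatch(
    data.table::fread(path, sep = sep, colClasses = list(character = concept_col),
                      showProgress = FALSE),
    error = function(e) stop_io(sprintf("cannot read %s: %s", path, conditionMessage(e)))
  )
  if (nrow(dt) == 0L) {
    warning("empty observation file: ", path)
    return(structure(list(), names = character(0)))
  }
  needed <- c(concept_col, value_col, id_col)
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols)) {
    stop_config(sprintf("missing column(s) in %s: %s", path,
                        paste(missing_cols, collapse = ", ")))
  }
  concept <- as.character(dt[[concept_col]])
  raw <- dt[[value_col]]
  value <- suppressWarnings(as.numeric(raw))
  ids <- if (is.null(id_col)) paste0("r", seq_len(nrow(dt))) else as.character(dt[[id_col]])
  ok <- is.finite(value)
  out <- lapply(split(seq_len(nrow(dt)), concept), function(i) {
    keep <- i[ok[i]]
    observation_series(value[keep], row_ids = ids[keep],
                       concept_code = concept[i[1]],
                       n_excluded = sum(!ok[i]))
  })
  # split() sorts by concept; keep first-appearance order of concepts instead
  out[order(match(names(out), unique(concept)))]
}

#' Construct a silver-standard plausibility interval
#'
#' A silver standard is a manually curated closed interval `[low, high]` of
#' plausible values for one observation type. Values strictly below `low` or
#' strictly above `high` are labelled implausible; the bounds themselves are
#' plausible. Standards are used only to *evaluate* the detector, never by
#' the detector itself.
#'
#' @param concept_code Observation-type identifier.
#' @param low,high Interval bounds, `low <= high`.
#' @return Object of class `silver_standard`.
#' @examples
#' silver_standard("10839-9", 0, 20)  # Troponin I cutoffs
#' @export
silver_standard <- function(concept_code, low, high) {
  low <- as.numeric(low); high <- as.numeric(high)
  if (is.na(low) || is.na(high)) {
    stop_validation(sprintf("silver standard for %s has missing bounds", concept_code))
  }
  if (low > high) {
    stop_validation(sprintf("silver standard for %s has low (%g) > high (%g)",
                            concept_code, low, high))
  }
  structure(list(concept_code = as.character(concept_code)[1],
                 low = low, high = high),
            class = "silver_standard")
}

#' @export
print.silver_standard <- function(x, ...) {
  cat(sprintf("<silver_standard> %s: plausible in [%g, %g]\n",
              x$concept_code, x$low, x$high))
  invisible(x)
}

#' Read a silver-standard table
#'
#' Expects a delimited file with columns `concept_code`, `low`, `high`,
#' one row per observation type.
#'
#' @param path Path to the table.
#' @return Named list mapping concept code to [silver_standard()].
#' @export
read_silver_standards <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("silver-standard file not found: %s", path))
  dt <- data.table::fread(path, showProgress = FALSE)
  missing_cols <- setdiff(c("concept_code", "low", "high"), names(dt))
  if (length(missing_cols)) {
    stop_config(sprintf("silver-standard table %s lacks column(s): %s", path,
                        paste(missing_cols, collapse = ", ")))
  }
  out <- lapply(seq_len(nrow(dt)), function(i) {
    silver_standard(dt$concept_code[i], dt$low[i], dt$high[i])
  })
  names(out) <- as.character(dt$concept_code)
  out
}

new_flag_report <- function(df) {
  cols <- c("row_id", "value", "flagged", "fold_index",
            "cluster_index", "cluster_population")
  stopifnot(identical(names(df), cols))
  if (anyDuplicated(df$row_id)) {
    stop_validation("flag report: duplicated row_id (folds must partition the data)")
  }
  class(df) <- c("flag_report", "data.frame")
  df
}

#' Write a flag report to delimited text
#'
#' The report has one row per input observation with columns `row_id`,
#' `value`, `flagged`, `fold_index`, `cluster_index`, `cluster_population`.
#' Writing then reading with [read_flag_report()] round-trips losslessly.
#'
#' @param report A `flag_report` as produced by [run_pipeline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flag_report <- function(report, path) {
  ok <- tryCatch({
    data.table::fwrite(as.data.frame(report), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Read a flag report written by [write_flag_report()]
#' @param path CSV path.
#' @return A `flag_report` data frame.
#' @export
read_flag_report <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("flag report not found: %s", path))
  dt <- data.table::fread(path, colClasses = list(character = "row_id"),
                          showProgress = FALSE)
  df <- as.data.frame(dt)
  if (nrow(df) == 0L) {
    df <- data.frame(row_id = character(0), value = numeric(0),
                     flagged = logical(0), fold_index = integer(0),
                     cluster_index = integer(0), cluster_population = integer(0))
  }
  df$flagged <- as.logical(df$flagged)
  df$fold_index <- as.integer(df$fold_index)
  df$cluster_index <- as.integer(df$cluster_index)
  df$cluster_population <- as.integer(df$cluster_population)
  new_flag_report(df)
}
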