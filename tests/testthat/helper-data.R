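# Small fixture builders shared across test files.

make_series <- function(values, code = "TEST") {
  observation_series(values, concept_code = code)
}

write_obs_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A quick-to-run pipeline configuration for unit tests (small folds).
tiny_config <- function(alpha = 1 / 50, seed = 1, ...) {
  flag_config(alpha = alpha, seed = seed, ...)
}
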