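# Internal validation helpers. All user-facing errors are classed so callers
# (and the pipeline driver) can distinguish bad inputs from bugs.

stop_invalid <- function(msg, class = "cnvchemo_invalid_input") {
  rlang::abort(msg, class = c(class, "cnvchemo_error"))
}

stop_config <- function(msg) {
  stop_invalid(msg, class = "cnvchemo_config_error")
}

stop_degenerate <- function(msg) {
  stop_invalid(msg, class = "cnvchemo_degenerate_input")
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive number, got %s",
                         name, deparse(substitute(x))))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_invalid(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Derive a stream-specific child seed from one master seed so that adding a
# generator never perturbs fixtures produced by the others. Kept below 2^31.
child_seed <- function(seed, stream) {
  offsets <- c(depth = 11L, tree = 23L, traits = 37L, codon = 53L,
               expression = 71L, cohort = 89L, fixture = 101L)
  if (!stream %in% names(offsets)) {
    stop_invalid(sprintf("unknown seed stream '%s'", stream))
  }
  (as.integer(seed) * 1000L + offsets[[stream]]) %% 2147483647L
}
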