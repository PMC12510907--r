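# Internal helpers shared across modules.

# Derive n child seeds from one parent seed without disturbing the caller's
# RNG state. Used to give each pipeline stage (simulation, bootstrap, MCMC,
# evaluation replicates) its own stream, so e.g. changing the bootstrap B
# cannot perturb data generation.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a class so callers can distinguish configuration errors from
# data errors programmatically.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sirvar_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("sirvar_data_error", "error")))
}

# format a confidence level as a column suffix: 0.95 -> "95", 0.998 -> "998"
fmt_level <- function(level) {
  gsub("\\.", "", sub("0+$", "", format(100 * level, trim = TRUE)))
}
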