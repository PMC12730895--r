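# Error helpers: every user-facing failure carries a motiscore_* condition
# class so callers and tests can target the failure mode, not the message.

abort_format <- function(msg, ...) {
  abort(msg, class = c("motiscore_format_error", "motiscore_error"), ...)
}

abort_vocab <- function(msg, ...) {
  abort(msg, class = c("motiscore_vocabulary_error", "motiscore_error"), ...)
}

abort_integrity <- function(msg, ...) {
  abort(msg, class = c("motiscore_integrity_error", "motiscore_error"), ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = c("motiscore_config_error", "motiscore_error"), ...)
}

abort_scoring <- function(msg, ...) {
  abort(msg, class = c("motiscore_scoring_error", "motiscore_error"), ...)
}

abort_data <- function(msg, ...) {
  abort(msg, class = c("motiscore_data_error", "motiscore_error"), ...)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "%s is missing mandatory column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic per-purpose stream seeds derived from one root seed, so
# draws for one component do not depend on how many draws another made.
# Multiplier is the MINSTD LCG constant; modulus keeps seeds in 32-bit range.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  as.integer((abs(as.double(seed)) * 48271 + as.double(index) * 2654435) %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}
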