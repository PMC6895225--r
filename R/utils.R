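# Internal helpers shared across modules.

#' Run code under a local RNG seed
#'
#' If `seed` is NULL the current RNG stream is used (and advanced); otherwise
#' the code runs under `set.seed(seed)` and the caller's RNG state is restored
#' afterwards. All user-facing stochastic entry points funnel through this so
#' that seeding is consistent package-wide.
#'
#' @param seed integer scalar or NULL.
#' @param code expression to evaluate.
#' @noRd
with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

#' Derive a deterministic sequence of child seeds from a master seed
#'
#' Child seeds are drawn from the stream started at the master seed, keeping
#' them independent of how many are requested before any given index. Values
#' stay strictly below 2^31 (R integers are 32-bit).
#'
#' @noRd
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

stop_focs <- function(..., class = "focs_error", call. = FALSE) {
  msg <- paste0(...)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
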