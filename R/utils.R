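#' Derive a child seed from a master seed and a stage tag
#'
#' All stochastic operations in the package draw their randomness from a
#' child seed derived deterministically from one master seed and a short
#' character tag, so that a single `seed` reproduces a whole pipeline run
#' while stages stay independent of each other's draw order.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the stage (e.g. `"depths"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483646 + 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

md_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
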