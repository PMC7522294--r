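# Internal helpers shared across modules.

#' Derive a stage-specific sub-seed from a global seed
#'
#' Stage seeds are derived deterministically from one global seed so that
#' independent stages never consume the same random stream. The derivation
#' (a fixed-multiplier hash of the stage name, reduced modulo 2^31 - 1) is
#' recorded in workflow manifests.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 10007 + h * 2654435) %% 2147483646) + 1L
}

clip01 <- function(x) {
  # preserves names/dim (pmax(0, x) would drop them)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Evaluate `code` under a fixed seed without touching the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
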