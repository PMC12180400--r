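# Internal helpers shared across modules.

#' @keywords internal
.methods <- c("PC", "ARU", "KBM")

#' @keywords internal
.cues <- c("heard", "seen", "unknown")

#' @keywords internal
.layers <- c("foreground", "background", "n/a")

# Derive a reproducible child seed for a named stage from a base seed.
# Kept below 2^31 (R integers are 32-bit).
#' @keywords internal
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate_pc = 11L, simulate_aru = 23L, simulate_kbm = 37L,
    simulate_emb = 41L, accumulate = 53L, occurrence = 67L,
    compare = 71L, classify = 83L, report = 97L
  )
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 1009 + off) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
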