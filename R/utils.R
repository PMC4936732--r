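# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Half-up decimal rounding (base round() is banker's).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(master, offset) {
  (as.integer(master) * 1009L + as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
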