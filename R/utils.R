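# Internal helpers: RNG stream handling and small assertions.

# Derive a deterministic sub-seed from (seed, operation name, iteration).
# Multipliers kept small so all arithmetic stays exact in doubles and the
# result stays below 2^31 (R integer range).
.derive_seed <- function(seed, op, i = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((abs(seed) * 7919 + h * 104729 + i * 15485863) %% 2147483647)
}

# Save/restore the global RNG state so stochastic package functions do not
# disturb the caller's random number stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
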