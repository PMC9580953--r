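# Internal helpers.

# Truncate (not round) to `digits` decimals. A 1e-9 nudge guards against
# values like 48.60 being represented as 48.5999... in binary.
truncateDecimals <- function(x, digits = 2L) {
  f <- 10^digits
  trunc(x * f + 1e-9) / f
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

assertCount <- function(x, name, min = 0L) {
  if (length(x) != 1 || is.na(x) || x < min || x != as.integer(x))
    stop(sprintf("%s must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
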