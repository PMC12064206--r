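# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that seeded package functions do not disturb user scripts.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number or NULL.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf(
      "`%s` must be a single number in [%s, %s].", name,
      format(lower), format(upper)
    ))
  }
  invisible(x)
}

# Shannon entropy (nats) of a nonnegative weight vector, normalised to sum 1.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

# Competition ("1224") ranking on descending values: ties share the smallest
# applicable rank and the next distinct value skips ranks.
competition_rank <- function(x) {
  rank(-x, ties.method = "min")
}
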