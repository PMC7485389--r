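# x * log2(x) with the 0 log 0 = 0 convention; the building block of all
# map-equation terms.
plogp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# Shannon entropy (bits) of a probability vector (renormalised defensively).
entropy_bits <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(plogp(p))
}

# Run an expression with a locally seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number in (0, 1), got %s.",
                  name, deparse(x)))
  }
  invisible(x)
}
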