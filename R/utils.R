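# Internal helpers: seed fan-out and RNG hygiene.
#
# One user-facing seed controls every stochastic operation; each operation
# draws from its own named sub-stream so parts of a pipeline can be rerun
# independently with identical results.

.subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) %% 2147480000 * 1009 + h * 7919 + 1) %% 2147483629)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL uses the ambient stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.assertCount <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be an integer count >= %d", name, min))
  as.integer(x)
}

.colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}
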