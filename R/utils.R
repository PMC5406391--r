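# Internal helpers: seeded RNG discipline and small numeric utilities.

# Derive a child seed (< 2^31) deterministically from a base seed and any
# number of integer tags. Linear-congruential folding over a Mersenne prime.
derive_seed <- function(base, ...) {
  tags <- c(base, ...)
  m <- 2147483647
  s <- 0
  for (k in tags) {
    s <- (s * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(s)
}

# Evaluate expr under a local RNG seed, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Excess-free (Pearson) kurtosis: E[(x-mu)^4] / sd^4.
pearson_kurtosis <- function(x) {
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - mu)^4) / s2^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
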