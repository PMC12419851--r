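# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is required (reproducibility is mandatory)",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean and variance of a Normal(mu, sd^2) truncated to [lo, hi].
truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  za <- stats::dnorm(a); zb <- stats::dnorm(b)
  pa <- stats::pnorm(a); pb <- stats::pnorm(b)
  Z <- pb - pa
  if (Z <= 0) stopf("empty truncation interval [%g, %g]", lo, hi)
  m <- mu + sd * (za - zb) / Z
  v <- sd^2 * (1 + (a * za - b * zb) / Z - ((za - zb) / Z)^2)
  list(mean = m, var = v)
}

# Draw from Normal(mu, sd^2) truncated to [lo, hi] by inverse CDF.
rtruncnorm <- function(n, mu, sd, lo, hi) {
  pa <- stats::pnorm(lo, mu, sd)
  pb <- stats::pnorm(hi, mu, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mu, sd)
}
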