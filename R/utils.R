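# Internal numerical helpers. All tail probabilities in this package are
# accumulated in the log domain so that values far below double underflow
# (the reliability targets of interest sit near 1e-14 and below) keep full
# relative accuracy.

logadd <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# x * log(y) with the 0 * log(0) = 0 convention
xlogy <- function(x, y) {
  out <- rep(0, length(x))
  nz <- x != 0
  out[nz] <- x[nz] * log(y)
  out
}

# log P[X >= kmin] for X ~ Binomial(n, p), exact log-domain sum
lbinom_tail <- function(n, p, kmin) {
  if (kmin <= 0) return(0)
  if (kmin > n) return(-Inf)
  logsumexp(stats::dbinom(kmin:n, n, p, log = TRUE))
}

# Vector of upper-tail log probabilities: element d + 1 is log P[X >= d]
# for d = 0..n+1 (the last entry is -Inf). One O(n) pass shared by all
# cutoffs, used by the density optimizer.
lbinom_tail_all <- function(n, p) {
  lp <- stats::dbinom(0:n, n, p, log = TRUE)
  out <- numeric(n + 2)
  out[n + 2] <- -Inf
  acc <- -Inf
  for (k in n:0) {
    acc <- logadd(acc, lp[k + 1])
    out[k + 1] <- acc
  }
  out[1] <- 0 # P[X >= 0] is exactly 1
  out
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) ||
      any(x != floor(x))) {
    stop(sprintf("`%s` must be integer-valued and >= %d", name, min),
         call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; used by all seeded simulation entry points.
with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic per-block seeds derived from one user seed via a Lehmer
# multiplicative congruential stream (modulus 2^31 - 1; exact in doubles).
# Block b's seed depends only on (seed, b), so extending a simulation by
# more blocks never changes earlier blocks.
block_seeds <- function(seed, nblocks) {
  s <- (abs(as.numeric(seed)) %% 2147483646) + 1
  out <- integer(nblocks)
  for (i in seq_len(nblocks)) {
    s <- (48271 * s) %% 2147483647
    out[i] <- as.integer(s)
  }
  out
}
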