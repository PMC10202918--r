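# Internal helpers.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-(subject, trial) seed below 2^31 from the cohort seed.
trialSeed <- function(seed, subjIdx, trialIdx) {
  as.integer((as.double(seed) * 100003 + subjIdx * 7919 + trialIdx * 131) %%
               2147483647)
}

# Near-uniform point set on the unit sphere (Fibonacci lattice).
fibonacciSphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  v <- cbind(r * cos(phi), r * sin(phi), z)
  v / sqrt(rowSums(v^2))
}

# Uniformly random rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  qr0 <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr0)
  d <- sign(diag(qr.R(qr0)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Row indices of the k nearest rows of `ref` for each row of `query`,
# by Euclidean distance, computed in chunks to bound memory.
knnIndex <- function(query, ref, k, chunk = 2000L) {
  n <- nrow(query)
  out <- matrix(0L, n, k)
  refSq <- rowSums(ref^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(rowSums(query[idx, , drop = FALSE]^2), refSq, "+") -
      2 * query[idx, , drop = FALSE] %*% t(ref)
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

# Time axis (ms) of an epoch: sample k sits at tStart + (k-1)/fs*1000,
# so the sample at exactly tEnd is excluded.
epochTimesMs <- function(tStartMs, tEndMs, fsHz) {
  n <- round((tEndMs - tStartMs) / 1000 * fsHz)
  tStartMs + (seq_len(n) - 1) * 1000 / fsHz
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
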