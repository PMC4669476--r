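#' Enumerate muscle pairs
#'
#' Undirected pairs are the unordered combinations i < j in row-major order
#' ((1,2), (1,3), ..., (2,3), ...); directed pairs are all ordered
#' (source, target) combinations with source != target, source-major. Ten
#' channels give 45 undirected and 90 directed pairs.
#'
#' @param n number of channels.
#' @param directed logical; enumerate ordered pairs?
#' @return integer matrix with columns `from` and `to`.
#' @export
enumeratePairs <- function(n, directed = FALSE) {
  stopifnot(length(n) == 1L, n >= 1)
  if (directed) {
    from <- rep(seq_len(n), each = n)
    to <- rep(seq_len(n), times = n)
    keep <- from != to
    cbind(from = from[keep], to = to[keep])
  } else {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    cbind(from = idx[, 1L], to = idx[, 2L])
  }
}

# Deterministic sub-seed for substream `counter` of master seed `seed`.
# Linear counter scheme modulo the Mersenne prime 2^31 - 1; keeps derived
# seeds valid 32-bit integers and distinct for counters < 2^31 - 1.
subSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483647 +
                1000003 * as.numeric(counter)) %% 2147483647)
}

# Analytic signal via FFT half-spectrum doubling; x real vector.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase Butterworth filtering (forward-backward), order `ord` per pass.
zeroPhaseFilter <- function(x, fs, cutoff, type, ord = 4L) {
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("filter cutoff must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(ord, w, type = type)
  signal::filtfilt(bf, x)
}

# Band-limited unit-variance Gaussian noise, length n, band in Hz.
# Ideal (brick-wall) zero-phase band-pass by Fourier masking: exact
# band-limiting at any bandwidth, numerically stable where narrow IIR
# designs at high sampling rates are not.
bandNoise <- function(n, fs, band) {
  X <- stats::fft(stats::rnorm(n))
  f <- seq_len(n) - 1
  f <- pmin(f, n - f) * fs / n  # two-sided frequency magnitude
  X[f < band[1L] | f > band[2L]] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Companion-matrix spectral radius of a VAR coefficient list.
companionRadius <- function(A) {
  p <- length(A)
  m <- nrow(A[[1L]])
  C <- matrix(0, m * p, m * p)
  for (k in seq_len(p))
    C[seq_len(m), (k - 1) * m + seq_len(m)] <- A[[k]]
  if (p > 1)
    C[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

# Simulate a stable VAR process: n samples x m channels (after burn-in).
simulateVar <- function(n, A, Sigma, burn = 500L) {
  p <- length(A)
  m <- nrow(A[[1L]])
  L <- t(chol(Sigma))
  e <- L %*% matrix(stats::rnorm(m * (n + burn)), m)
  y <- matrix(0, m, n + burn)
  y[, seq_len(p)] <- e[, seq_len(p)]
  for (t in (p + 1):(n + burn)) {
    acc <- e[, t]
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% y[, t - k]
    y[, t] <- acc
  }
  y[, burn + seq_len(n), drop = FALSE]
}

# Area-under-ROC for scores of positives vs negatives (rank statistic).
rankAuc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
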