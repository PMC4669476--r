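# Welch-tapered short-time spectra of a channels x samples matrix.
# Returns complex array channels x frequency x window (one-sided grid).
welchSpectra <- function(x, fs, windowS = 1, overlapS = 0.75) {
  stopifnot(is.matrix(x), overlapS < windowS)
  n <- ncol(x)
  L <- round(windowS * fs)
  step <- round((windowS - overlapS) * fs)
  if (L > n) stop("window longer than the trial")
  nWin <- (n - L) %/% step + 1L
  taper <- signal::hamming(L)
  nf <- L %/% 2 + 1L
  freqs <- (seq_len(nf) - 1) * fs / L
  starts <- (seq_len(nWin) - 1L) * step
  out <- array(0 + 0i, dim = c(nrow(x), nf, nWin))
  for (ch in seq_len(nrow(x))) {
    seg <- matrix(0, L, nWin)
    for (w in seq_len(nWin)) seg[, w] <- x[ch, starts[w] + seq_len(L)]
    seg <- seg - rep(colMeans(seg), each = L)  # per-segment detrend (mean)
    out[ch, , ] <- stats::mvfft(seg * taper)[seq_len(nf), , drop = FALSE]
  }
  list(spectra = out, freqs = freqs, nWindows = nWin)
}

#' Welch complex coherency of one trial
#'
#' Estimates the complex-valued coherency between every unordered channel
#' pair from Hamming-tapered Welch windows (1-s windows, 0.75-s overlap by
#' default, giving a 1-Hz frequency grid):
#' `coherency_ij(f) = <X_i X_j*> / sqrt(<|X_i|^2><|X_j|^2>)` with `< >`
#' averaging over windows.
#'
#' @param x channels x samples numeric matrix (typically an envelope trial).
#' @param fs sampling rate in Hz.
#' @param windowS,overlapS Welch window length and overlap in seconds.
#' @param channelLabels optional channel labels.
#' @return a [CoherencyMatrix-class] with one row per unordered pair.
#' @export
welchCoherency <- function(x, fs, windowS = 1, overlapS = 0.75,
                           channelLabels = NULL) {
  sp <- welchSpectra(x, fs, windowS, overlapS)
  if (sp$nWindows < 2L)
    stop("coherency undefined: fewer than 2 Welch windows fit the trial")
  m <- nrow(x)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(m))
  pairs <- enumeratePairs(m, directed = FALSE)
  auto <- matrix(0, m, length(sp$freqs))
  for (ch in seq_len(m))
    auto[ch, ] <- rowMeans(Mod(sp$spectra[ch, , , drop = TRUE])^2)
  vals <- matrix(0 + 0i, nrow(pairs), length(sp$freqs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    cross <- rowMeans(sp$spectra[i, , , drop = TRUE] *
                        Conj(sp$spectra[j, , , drop = TRUE]))
    vals[r, ] <- cross / sqrt(auto[i, ] * auto[j, ])
  }
  # guard against |coherency| = 1 + eps from round-off
  mag <- Mod(vals)
  over <- which(mag > 1)
  if (length(over)) vals[over] <- vals[over] / mag[over]
  new("CoherencyMatrix", values = vals, freqs = sp$freqs, pairs = pairs,
      nWindows = as.numeric(sp$nWindows), channelLabels = channelLabels)
}

#' Pool complex coherency across trials
#'
#' Averages complex-valued coherency across the trials of one condition and
#' squares the magnitude, yielding trial-pooled magnitude-squared coherence.
#' Phase-inconsistent coherency cancels under the complex average, so pooling
#' can only preserve or reduce single-trial magnitudes.
#'
#' @param trials list of [CoherencyMatrix-class] on identical grids.
#' @param subject,condition identifiers stored in the result.
#' @return an undirected [ConnectivitySpectra-class].
#' @export
poolCoherence <- function(trials, subject = NA_character_,
                          condition = NA_character_) {
  stopifnot(length(trials) >= 1L)
  f0 <- trials[[1L]]@freqs
  p0 <- trials[[1L]]@pairs
  for (tr in trials) {
    if (!isTRUE(all.equal(tr@freqs, f0)) || !identical(tr@pairs, p0))
      stop("trials must share the frequency grid and pair map")
  }
  acc <- Reduce(`+`, lapply(trials, function(tr) tr@values))
  pooled <- Mod(acc / length(trials))^2
  pooled[pooled > 1] <- 1
  new("ConnectivitySpectra", values = pooled, freqs = f0, pairs = p0,
      directed = FALSE, subject = as.character(subject),
      condition = as.character(condition),
      channelLabels = trials[[1L]]@channelLabels)
}

# Fourier phase randomization preserving the amplitude spectrum and
# conjugate symmetry (surrogate stays real-valued).
phaseRandomize <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (half > 0) {
    ph <- stats::runif(half, 0, 2 * pi)
    idx <- 2:(half + 1)
    X[idx] <- X[idx] * exp(1i * ph)
    X[n + 2 - idx] <- Conj(X[idx])
  }
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Surrogate confidence threshold for pooled coherence
#'
#' Builds the null distribution of trial-pooled magnitude-squared coherence
#' by Fourier phase randomization: in each surrogate every channel of every
#' trial gets independent random phases (amplitude spectrum preserved), the
#' full pooling pipeline is re-run, and the per-pair, per-frequency
#' `1 - alpha` quantile across surrogates is returned as the confidence
#' limit.
#'
#' By default the envelopes themselves are randomized; with
#' `randomize = "raw"` the raw EMG is randomized and envelope extraction is
#' re-run on each surrogate.
#'
#' @param trials list of channels x samples matrices (envelope trials, or
#'   raw trials when `randomize = "raw"`).
#' @param fs sampling rate in Hz.
#' @param nSurrogates number of surrogates (>= 2).
#' @param alpha upper tail probability of the confidence limit.
#' @param seed integer seed.
#' @param windowS,overlapS Welch parameters passed to [welchCoherency()].
#' @param randomize `"envelope"` or `"raw"`.
#' @param cutoff high-pass cut-off used when `randomize = "raw"`.
#' @return list of class `SurrogateThreshold` with elements `thresholds`
#'   (pairs x frequency), `freqs`, `pairs`, `nSurrogates`, `alpha`.
#' @export
surrogateThreshold <- function(trials, fs, nSurrogates = 200, alpha = 0.05,
                               seed = 1L, windowS = 1, overlapS = 0.75,
                               randomize = c("envelope", "raw"),
                               cutoff = 20) {
  randomize <- match.arg(randomize)
  if (length(trials) < 1L) stop("'trials' must be non-empty")
  if (nSurrogates < 2L) stop("need at least 2 surrogates")
  set.seed(seed)
  stash <- NULL
  for (s in seq_len(nSurrogates)) {
    cohs <- lapply(trials, function(x) {
      xs <- t(apply(x, 1L, phaseRandomize))
      if (randomize == "raw") xs <- envelopeTrial(xs, fs, cutoff)
      welchCoherency(xs, fs, windowS, overlapS)
    })
    pooled <- poolCoherence(cohs)
    if (is.null(stash))
      stash <- array(0, dim = c(dim(pooled@values), nSurrogates))
    stash[, , s] <- pooled@values
    if (s == 1L) {
      freqs <- pooled@freqs
      pairs <- pooled@pairs
    }
  }
  thr <- apply(stash, c(1L, 2L), stats::quantile, probs = 1 - alpha,
               names = FALSE)
  structure(list(thresholds = thr, freqs = freqs, pairs = pairs,
                 nSurrogates = as.integer(nSurrogates), alpha = alpha),
            class = "SurrogateThreshold")
}
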