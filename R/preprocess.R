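#' Extract EMG amplitude envelopes (coherence branch)
#'
#' High-pass filters each channel (zero-phase Butterworth, 20 Hz cut-off by
#' default) and rectifies it with the Hilbert transform: the output is the
#' magnitude of the analytic signal, i.e. the instantaneous EMG amplitude
#' envelope, at the native sampling rate.
#'
#' @param study an [EmgStudy-class] with branch `"raw"`, or a numeric
#'   channels x samples matrix.
#' @param cutoff high-pass cut-off in Hz; must be below the Nyquist rate.
#' @param fs sampling rate, required when `study` is a bare matrix.
#' @return an envelope study (branch `"envelope"`) or matrix.
#' @export
highpassRectify <- function(study, cutoff = 20, fs = NULL) {
  if (is.matrix(study)) {
    if (is.null(fs)) stop("'fs' is required for matrix input")
    return(envelopeTrial(study, fs, cutoff))
  }
  stopifnot(is(study, "EmgStudy"))
  out <- study
  out@trials <- lapply(study@trials, envelopeTrial, fs = study@fs,
                       cutoff = cutoff)
  out@branch <- "envelope"
  validObject(out)
  out
}

envelopeTrial <- function(x, fs, cutoff) {
  if (cutoff >= fs / 2)
    stop("high-pass cutoff must be below the Nyquist frequency")
  t(apply(x, 1L, function(ch) {
    if (all(ch == 0)) return(ch)
    Mod(analyticSignal(zeroPhaseFilter(ch, fs, cutoff, "high")))
  }))
}

#' Condition envelopes for MVAR fitting
#'
#' Band-pass filters the envelopes (0.5-70 Hz, zero-phase Butterworth),
#' downsamples to 200 Hz (plain decimation when the rate ratio is an integer
#' - the band-pass already acts as the anti-alias filter - and polyphase
#' resampling otherwise) and z-scores every channel to zero mean and unit
#' variance.
#'
#' @param study envelope [EmgStudy-class] (branch `"envelope"`) or matrix.
#' @param band band-pass edges in Hz; the upper edge must be below
#'   `fsOut / 2`.
#' @param fsOut output sampling rate in Hz.
#' @param fs input sampling rate, required for matrix input.
#' @return study with branch `"mvar"` at `fsOut`, or a matrix.
#' @export
conditionForMvar <- function(study, band = c(0.5, 70), fsOut = 200,
                             fs = NULL) {
  if (is.matrix(study)) {
    if (is.null(fs)) stop("'fs' is required for matrix input")
    return(mvarTrial(study, fs, band, fsOut))
  }
  stopifnot(is(study, "EmgStudy"))
  out <- study
  out@trials <- lapply(study@trials, mvarTrial, fs = study@fs, band = band,
                       fsOut = fsOut)
  out@fs <- fsOut
  out@branch <- "mvar"
  validObject(out)
  out
}

# Low-pass (anti-alias) at the native rate, downsample, then band-pass at
# the output rate; the band-pass is applied after downsampling because
# narrow IIR designs relative to a high sampling rate are numerically
# fragile, and the result is identical in the passband.
mvarTrial <- function(x, fs, band, fsOut) {
  if (band[2L] >= fsOut / 2)
    stop("band upper edge must be below fsOut/2")
  if (fsOut > fs) stop("fsOut must not exceed the input rate")
  vr <- apply(x, 1L, stats::var)
  if (any(vr == 0))
    stop("degenerate (zero-variance) channel(s): ",
         paste(which(vr == 0), collapse = ", "))
  n <- ncol(x)
  nOut <- round(n * fsOut / fs)
  ratio <- fs / fsOut
  y <- t(apply(x, 1L, function(ch) {
    f <- zeroPhaseFilter(ch, fs, band[2L], "low")
    d <- if (abs(ratio - round(ratio)) < 1e-9) {
      f[seq(1L, n, by = round(ratio))][seq_len(nOut)]
    } else {
      as.numeric(signal::resample(f, p = fsOut, q = fs))[seq_len(nOut)]
    }
    zeroPhaseFilter(d, fsOut, band, "pass")
  }))
  y <- y - rowMeans(y)
  y / apply(y, 1L, stats::sd)
}

#' Normalized Welch power spectral density
#'
#' Welch PSD per channel (Hamming taper, 1-s windows with 0.75-s overlap by
#' default), normalized so that each channel's spectrum sums to 1 over the
#' analysis band.
#'
#' @param x numeric channels x samples matrix (e.g. an envelope trial).
#' @param fs sampling rate in Hz.
#' @param windowS window length in seconds.
#' @param overlapS window overlap in seconds.
#' @param band frequency band over which to report and normalize, in Hz.
#' @return list with `freqs` and `psd` (channels x frequency; rows sum to 1).
#' @export
normalizedPsd <- function(x, fs, windowS = 1, overlapS = 0.75,
                          band = c(0, fs / 2)) {
  stopifnot(is.matrix(x))
  sp <- welchSpectra(x, fs, windowS, overlapS)
  psd <- apply(Mod(sp$spectra)^2, c(1L, 2L), mean)
  keep <- sp$freqs >= band[1L] & sp$freqs <= band[2L]
  psd <- psd[, keep, drop = FALSE]
  tot <- rowSums(psd)
  if (any(tot == 0))
    stop("degenerate zero-power channel(s): ",
         paste(which(tot == 0), collapse = ", "))
  list(freqs = sp$freqs[keep], psd = psd / tot)
}
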