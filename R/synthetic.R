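#' Study design for synthetic EMG generation
#'
#' Describes the recording geometry the generator emulates: by default ten
#' bilateral leg muscles (RF, VM, GM, TA, ED on each side) sampled at 2 kHz,
#' 60-s trials, four trials in each of four conditions.
#'
#' @param nSubjects number of subjects.
#' @param conditions ordered character vector of condition labels.
#' @param trialsPerCondition trials per condition and subject.
#' @param trialDuration trial length in seconds.
#' @param fs sampling rate in Hz.
#' @param channelLabels unique channel (muscle) labels.
#' @return a `StudyDesign` list.
#' @export
studyDesign <- function(nSubjects = 18L,
                        conditions = c("control", "counting", "cup", "height"),
                        trialsPerCondition = 4L,
                        trialDuration = 60,
                        fs = 2000,
                        channelLabels = paste0(
                          rep(c("RF", "VM", "GM", "TA", "ED"), 2L),
                          rep(c("_r", "_l"), each = 5L))) {
  stopifnot(nSubjects >= 1, trialsPerCondition >= 1, trialDuration > 0,
            fs > 0, length(conditions) >= 1)
  if (anyDuplicated(channelLabels))
    stop("channel labels must be unique")
  n <- trialDuration * fs
  if (abs(n - round(n)) > 1e-9)
    stop("trialDuration * fs must be an integer sample count")
  structure(list(nSubjects = as.integer(nSubjects),
                 conditions = as.character(conditions),
                 trialsPerCondition = as.integer(trialsPerCondition),
                 trialDuration = trialDuration,
                 fs = fs,
                 channelLabels = channelLabels),
            class = "StudyDesign")
}

#' Band-limited common drive specification
#'
#' A common drive is a shared narrow-band input modulating the envelopes of a
#' set of target channels; channel pairs sharing a drive become coherent
#' inside the drive's band, the planted ground truth for undirected networks.
#'
#' @param centerFreq drive center frequency in Hz; must satisfy
#'   `centerFreq - bandwidth/2 > 0`.
#' @param bandwidth drive bandwidth in Hz, positive.
#' @param targets integer vector of target channel indices (1-based),
#'   non-empty.
#' @param gain nonnegative modulation depth applied to each target.
#' @return a `DriveSpec` list.
#' @export
driveSpec <- function(centerFreq, bandwidth, targets, gain) {
  stopifnot(length(centerFreq) == 1L, length(bandwidth) == 1L,
            length(gain) == 1L)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (centerFreq - bandwidth / 2 <= 0)
    stop("centerFreq - bandwidth/2 must be positive")
  if (gain < 0) stop("gain must be nonnegative")
  targets <- as.integer(targets)
  if (length(targets) == 0L || anyDuplicated(targets) || any(targets < 1))
    stop("targets must be a non-empty set of positive channel indices")
  structure(list(centerFreq = centerFreq, bandwidth = bandwidth,
                 targets = targets, gain = gain),
            class = "DriveSpec")
}

#' Directed envelope coupling specification
#'
#' A stable VAR model over envelope modulators: the generative twin of the
#' MVAR model the pipeline fits. The companion-matrix spectral radius must be
#' below 1 and the noise covariance symmetric positive definite.
#'
#' @param A list of lag coefficient matrices (channels x channels).
#' @param Sigma innovation covariance matrix.
#' @return a `VarCouplingSpec` list.
#' @export
varCouplingSpec <- function(A, Sigma) {
  stopifnot(is.list(A), length(A) >= 1L)
  m <- nrow(A[[1L]])
  for (Ak in A) stopifnot(is.matrix(Ak), all(dim(Ak) == c(m, m)))
  stopifnot(is.matrix(Sigma), all(dim(Sigma) == c(m, m)))
  if (max(abs(Sigma - t(Sigma))) > 1e-10)
    stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  rho <- companionRadius(A)
  if (rho >= 1)
    stop(sprintf("unstable VAR coefficients (spectral radius %.3f >= 1)", rho))
  structure(list(nChannels = m, order = length(A), A = A, Sigma = Sigma),
            class = "VarCouplingSpec")
}

#' Generate independent band-limited carrier EMG
#'
#' Produces one trial of mutually independent, zero-mean band-limited
#' Gaussian channels, emulating the acquisition bandwidth of surface EMG
#' (5-400 Hz band-pass at 2 kHz by default). Deterministic given the seed.
#'
#' @param nChannels number of channels.
#' @param design a [studyDesign()]; supplies fs and trial duration.
#' @param band carrier band (low, high) in Hz, inside (0, fs/2).
#' @param seed integer seed.
#' @return numeric matrix, channels x samples.
#' @export
generateCarrier <- function(nChannels, design, band = c(5, 400), seed = 1L) {
  stopifnot(inherits(design, "StudyDesign"))
  if (band[1L] <= 0 || band[2L] >= design$fs / 2 || band[1L] >= band[2L])
    stop("carrier band must lie inside (0, fs/2)")
  n <- round(design$trialDuration * design$fs)
  set.seed(seed)
  x <- matrix(0, nChannels, n)
  for (ch in seq_len(nChannels))
    x[ch, ] <- bandNoise(n, design$fs, band)
  x
}

# Build the study info table in subject-major, condition, trial order.
designInfo <- function(design) {
  g <- expand.grid(trial = seq_len(design$trialsPerCondition),
                   condition = design$conditions,
                   subject = sprintf("S%02d", seq_len(design$nSubjects)),
                   stringsAsFactors = FALSE)
  data.frame(subject = g$subject, condition = as.character(g$condition),
             trial = g$trial, stringsAsFactors = FALSE)
}

#' Generate a study with planted common drives
#'
#' Each channel is an independent band-limited carrier multiplied by a
#' positive modulator `1 + sum_d gain_d s_d(t)` where each drive signal
#' `s_d` is unit-variance Gaussian noise band-passed (zero phase) to its
#' drive band and shared across the drive's target channels. The modulator
#' is clipped from below at 0.05 so the envelope scale stays positive.
#' Envelope coherence between two channels sharing a drive is planted inside
#' that drive's band; all other pairs stay at the noise floor.
#'
#' Seeding: one master seed; each trial draws from a substream indexed by its
#' (subject, condition, trial) counter, so regenerating any subset of the
#' study is reproducible.
#'
#' @param design a [studyDesign()].
#' @param drives list of [driveSpec()] objects (may be empty).
#' @param seed master integer seed.
#' @param carrierBand carrier band in Hz.
#' @return an [EmgStudy-class] with branch `"raw"` and the generator spec in
#'   its provenance.
#' @export
generateCommonDriveStudy <- function(design, drives = list(), seed = 1L,
                                     carrierBand = c(5, 400)) {
  stopifnot(inherits(design, "StudyDesign"))
  nch <- length(design$channelLabels)
  for (d in drives) {
    if (!inherits(d, "DriveSpec")) stop("drives must be DriveSpec objects")
    if (any(d$targets > nch))
      stop("drive target indices exceed the number of channels")
    if (d$centerFreq + d$bandwidth / 2 >= design$fs / 2)
      stop("drive band exceeds the Nyquist frequency")
  }
  totalGain <- numeric(nch)
  for (d in drives) totalGain[d$targets] <- totalGain[d$targets] + d$gain
  if (any(totalGain > 2))
    stop("modulation depth too large: the envelope scale would be negative ",
         "on a substantial fraction of samples (total per-channel gain > 2)")
  info <- designInfo(design)
  n <- round(design$trialDuration * design$fs)
  trials <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    set.seed(subSeed(seed, i))
    s <- lapply(drives, function(d)
      bandNoise(n, design$fs,
                c(d$centerFreq - d$bandwidth / 2,
                  d$centerFreq + d$bandwidth / 2)))
    x <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      mod <- rep(1, n)
      for (k in seq_along(drives)) {
        d <- drives[[k]]
        if (ch %in% d$targets) mod <- mod + d$gain * s[[k]]
      }
      x[ch, ] <- bandNoise(n, design$fs, carrierBand) * pmax(mod, 0.05)
    }
    trials[[i]] <- x
  }
  new("EmgStudy", trials = trials, fs = design$fs,
      channelLabels = design$channelLabels, info = info, branch = "raw",
      provenance = list(generator = "common_drive", design = design,
                        drives = drives, seed = as.integer(seed),
                        carrierBand = carrierBand))
}

# Stationary covariance of a stable VAR via the companion-form Lyapunov
# equation; returns the m x m lag-0 covariance.
varStationaryCov <- function(A, Sigma) {
  p <- length(A)
  m <- nrow(A[[1L]])
  C <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) C[seq_len(m), (k - 1) * m + seq_len(m)] <- A[[k]]
  if (p > 1) C[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  Sc <- matrix(0, m * p, m * p)
  Sc[seq_len(m), seq_len(m)] <- Sigma
  G <- solve(diag((m * p)^2) - kronecker(C, C), as.vector(Sc))
  matrix(G, m * p, m * p)[seq_len(m), seq_len(m)]
}

#' Generate a study with planted directed envelope coupling
#'
#' Envelope-level dynamics follow a stable VAR: the coupling process is
#' simulated at the envelope rate (200 Hz), rescaled so every channel has
#' unit stationary variance (the pipeline z-scores envelopes, so this keeps
#' the planted coefficients comparable to the fitted ones), linearly
#' interpolated to the carrier rate and applied as a multiplicative modulator
#' `max(1 + depth * z, 0.05)` on independent band-limited carriers.
#'
#' The squared partial directed coherence of the variance-scaled coefficients
#' is the planted directed ground truth; it is stored in the study provenance
#' (`scaledA`, `scaledSigma`, `envFs`) and can be evaluated on any frequency
#' grid with [pdcFromCoefficients()].
#'
#' @param design a [studyDesign()]; `channelLabels` must match the coupling
#'   dimension.
#' @param coupling a [varCouplingSpec()].
#' @param seed master integer seed.
#' @param depth modulation depth applied to the unit-variance VAR channels.
#' @param envFs rate (Hz) at which the envelope VAR is simulated.
#' @param carrierBand carrier band in Hz.
#' @return an [EmgStudy-class] with branch `"raw"`.
#' @export
generateVarEnvelopeStudy <- function(design, coupling, seed = 1L,
                                     depth = 0.4, envFs = 200,
                                     carrierBand = c(5, 400)) {
  stopifnot(inherits(design, "StudyDesign"),
            inherits(coupling, "VarCouplingSpec"))
  nch <- length(design$channelLabels)
  if (coupling$nChannels != nch)
    stop("coupling dimension does not match the number of channels")
  sdv <- sqrt(diag(varStationaryCov(coupling$A, coupling$Sigma)))
  D <- diag(1 / sdv, nch)
  Dinv <- diag(sdv, nch)
  scaledA <- lapply(coupling$A, function(Ak) D %*% Ak %*% Dinv)
  scaledSigma <- D %*% coupling$Sigma %*% D
  info <- designInfo(design)
  n <- round(design$trialDuration * design$fs)
  nEnv <- round(design$trialDuration * envFs)
  tEnv <- (seq_len(nEnv) - 1) / envFs
  tFull <- (seq_len(n) - 1) / design$fs
  trials <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    set.seed(subSeed(seed, i))
    z <- simulateVar(nEnv, scaledA, scaledSigma)
    x <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      zUp <- stats::approx(tEnv, z[ch, ], xout = tFull, rule = 2)$y
      x[ch, ] <- bandNoise(n, design$fs, carrierBand) *
        pmax(1 + depth * zUp, 0.05)
    }
    trials[[i]] <- x
  }
  new("EmgStudy", trials = trials, fs = design$fs,
      channelLabels = design$channelLabels, info = info, branch = "raw",
      provenance = list(generator = "var_envelope", design = design,
                        coupling = coupling, scaledA = scaledA,
                        scaledSigma = scaledSigma, envFs = envFs,
                        depth = depth, seed = as.integer(seed),
                        carrierBand = carrierBand))
}
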