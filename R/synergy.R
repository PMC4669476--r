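#' Condition envelopes for time-domain synergy extraction
#'
#' Low-pass filters the amplitude envelopes (10 Hz, zero-phase Butterworth)
#' and downsamples to 100 Hz, clipping tiny negative filter overshoots to
#' zero so the matrix stays valid NMF input.
#'
#' @param x nonnegative channels x samples envelope matrix.
#' @param fs sampling rate of `x` in Hz.
#' @param lowpass low-pass cut-off in Hz.
#' @param fsOut output rate in Hz.
#' @return nonnegative channels x samples matrix at `fsOut`.
#' @export
conditionForSynergy <- function(x, fs, lowpass = 10, fsOut = 100) {
  stopifnot(is.matrix(x), fsOut <= fs, lowpass < fsOut / 2)
  n <- ncol(x)
  nOut <- round(n * fsOut / fs)
  ratio <- fs / fsOut
  t(apply(x, 1L, function(ch) {
    f <- zeroPhaseFilter(ch, fs, lowpass, "low")
    y <- if (abs(ratio - round(ratio)) < 1e-9) {
      f[seq(1L, n, by = round(ratio))][seq_len(nOut)]
    } else {
      as.numeric(signal::resample(f, p = fsOut, q = fs))[seq_len(nOut)]
    }
    pmax(y, 0)
  }))
}

#' Estimate the number of synergies by PCA
#'
#' Number of principal components of the muscle x time envelope matrix
#' needed to explain the target fraction (90% by default) of the variance,
#' plus the full cumulative variance-explained curve.
#'
#' @param x muscles x time envelope matrix (>= 2 muscles, >= 2 samples).
#' @param varianceTarget cumulative variance fraction to reach.
#' @return list with `n` and `curve` (cumulative fractions, ending at 1).
#' @export
estimateNSynergies <- function(x, varianceTarget = 0.90) {
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) >= 2)
  v <- apply(x, 1L, stats::var)
  if (all(v == 0)) stop("degenerate input: zero variance")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  curve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  list(n = which(curve >= varianceTarget - 1e-12)[1L], curve = curve)
}

#' Extract muscle synergies by NMF
#'
#' Factorizes the nonnegative muscle x time envelope matrix into synergy
#' basis vectors (muscle weight profiles, unit-norm columns) and activation
#' time courses using the same alternating-least-squares engine as the
#' spectral unmixing. Deterministic given the seed.
#'
#' @param x nonnegative muscles x time matrix.
#' @param nSynergies number of synergies to extract.
#' @param seed integer seed.
#' @param subject,condition identifiers stored in the result.
#' @param channelLabels muscle labels.
#' @inheritParams nmfAls
#' @return a [SynergySet-class].
#' @export
extractSynergies <- function(x, nSynergies, seed = 1L,
                             subject = NA_character_,
                             condition = NA_character_,
                             channelLabels = NULL,
                             tol = 1e-6, maxIter = 500, nRestarts = 10) {
  stopifnot(is.matrix(x))
  if (any(x < 0)) stop("envelopes must be nonnegative")
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(nrow(x)))
  fit <- nmfAls(x, k = nSynergies, tol = tol, maxIter = maxIter,
                nRestarts = nRestarts, seed = seed)
  nrm <- sqrt(colSums(fit$W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(fit$W, 2L, nrm, `/`)
  H <- sweep(fit$H, 1L, nrm, `*`)
  new("SynergySet", basis = W, activations = H,
      varianceExplained = estimateNSynergies(x)$curve,
      subject = as.character(subject), condition = as.character(condition),
      channelLabels = channelLabels)
}

permutationsOf <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Align synergy sets across subjects and conditions
#'
#' Reorders the basis vectors of each set by the permutation that maximizes
#' the total correlation with a reference set (exhaustive optimal assignment
#' over the pairwise correlation matrix; basis nonnegativity forbids general
#' rotations, so alignment is by permutation). Returns the aligned sets and
#' a per-synergy consistency score: the mean pairwise correlation between
#' aligned basis vectors across sets.
#'
#' @param sets list of [SynergySet-class] with equal synergy counts.
#' @param reference a [SynergySet-class]; defaults to the first set.
#' @return list with `sets` (aligned), `permutations` (one row per set) and
#'   `consistency` (length-K numeric).
#' @export
alignSynergies <- function(sets, reference = sets[[1L]]) {
  stopifnot(length(sets) >= 1L)
  k <- ncol(reference@basis)
  for (s in sets)
    if (ncol(s@basis) != k)
      stop("all sets must have the same number of synergies")
  if (k > 8L) stop("exhaustive alignment supported for up to 8 synergies")
  perms <- permutationsOf(k)
  aligned <- vector("list", length(sets))
  permUsed <- matrix(0L, length(sets), k)
  for (si in seq_along(sets)) {
    s <- sets[[si]]
    C <- outer(seq_len(k), seq_len(k), Vectorize(function(r, c)
      safeCor(reference@basis[, r], s@basis[, c])))
    scores <- apply(perms, 1L, function(p) sum(C[cbind(seq_len(k), p)]))
    best <- perms[which.max(scores), ]
    s@basis <- s@basis[, best, drop = FALSE]
    s@activations <- s@activations[best, , drop = FALSE]
    aligned[[si]] <- s
    permUsed[si, ] <- best
  }
  consistency <- vapply(seq_len(k), function(r) {
    if (length(aligned) < 2L) return(NA_real_)
    vecs <- lapply(aligned, function(s) s@basis[, r])
    cc <- utils::combn(length(vecs), 2L, function(ij)
      safeCor(vecs[[ij[1L]]], vecs[[ij[2L]]]))
    mean(cc)
  }, 0)
  list(sets = aligned, permutations = permUsed, consistency = consistency)
}
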