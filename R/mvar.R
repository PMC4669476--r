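#' Fit a strictly causal MVAR model by least squares
#'
#' Ordinary least-squares fit of the multivariate autoregression
#' `y_t = sum_k A_k y_{t-k} + e_t` to a conditioned (band-passed,
#' downsampled, z-scored) envelope trial. The residual covariance is the
#' maximum-likelihood estimate (divisor = number of regression samples).
#'
#' @param x channels x samples numeric matrix.
#' @param p model order (number of lags).
#' @param fs sampling rate of `x` in Hz.
#' @param channelLabels optional channel labels.
#' @return an [MvarModel-class].
#' @export
fitMvar <- function(x, p, fs = 200, channelLabels = NULL) {
  stopifnot(is.matrix(x), p >= 1)
  m <- nrow(x)
  n <- ncol(x)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(m))
  N <- n - p
  if (N <= m * p)
    stop("trial too short for the requested order")
  if (N <= 10 * p * m)
    warning("fewer than 10 samples per coefficient; estimates may be noisy")
  Y <- t(x[, (p + 1):n, drop = FALSE])
  Z <- matrix(0, N, m * p)
  for (k in seq_len(p))
    Z[, (k - 1) * m + seq_len(m)] <- t(x[, (p + 1 - k):(n - k), drop = FALSE])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    cc <- stats::cor(t(x))
    dup <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
    hint <- if (nrow(dup)) {
      paste0(" (collinear channels: ",
             paste(apply(dup, 1L, paste, collapse = "~"), collapse = ", "),
             ")")
    } else ""
    stop("singular MVAR regression", hint)
  }
  beta <- qr.coef(qz, Y)
  res <- Y - Z %*% beta
  Sigma <- crossprod(res) / N
  Sigma <- (Sigma + t(Sigma)) / 2
  A <- lapply(seq_len(p), function(k)
    t(beta[(k - 1) * m + seq_len(m), , drop = FALSE]))
  new("MvarModel", order = as.integer(p), A = A, B0 = NULL, Sigma = Sigma,
      fs = fs, nSamples = as.integer(N), channelLabels = channelLabels,
      ordering = integer())
}

#' Select MVAR model order by AIC
#'
#' Fits orders 1..`pMax` and returns the minimizer of
#' `AIC(p) = ln det(Sigma_p) + 2 p M^2 / N`, where M is the number of
#' channels and N the number of regression samples at order p, together with
#' the full criterion curve.
#'
#' @param x channels x samples numeric matrix.
#' @param pMax maximum candidate order.
#' @param fs sampling rate in Hz.
#' @return list with `order` (selected), `aic` (length `pMax`).
#' @export
selectOrderAic <- function(x, pMax = 30, fs = 200) {
  m <- nrow(x)
  aic <- rep(NA_real_, pMax)
  for (p in seq_len(pMax)) {
    fit <- suppressWarnings(fitMvar(x, p, fs))
    ld <- determinant(fit@Sigma, logarithm = TRUE)
    if (ld$sign <= 0 || !is.finite(ld$modulus))
      stop("degenerate residual covariance at order ", p)
    aic[p] <- as.numeric(ld$modulus) + 2 * p * m^2 / fit@nSamples
  }
  list(order = which.min(aic), aic = aic)
}

#' Identify instantaneous effects (extended MVAR)
#'
#' Augments a strictly causal MVAR model with an instantaneous (lag-zero)
#' coefficient matrix `B0` obtained from the unit-diagonal Cholesky (LDL)
#' factorization of the residual covariance under a supplied causal channel
#' ordering. The lagged coefficients are re-expressed accordingly and the
#' residual covariance of the extended model is diagonal. The model-implied
#' spectral matrix is unchanged by this refactorization; only the attribution
#' of zero-lag correlation to directed instantaneous paths depends on the
#' ordering, which is therefore recorded in the result.
#'
#' @param model an [MvarModel-class] with positive-definite residual
#'   covariance.
#' @param ordering integer permutation of channels: the assumed causal order
#'   of instantaneous effects (earlier channels may affect later ones).
#' @return an extended [MvarModel-class] with `B0` and diagonal `Sigma`.
#' @export
identifyInstantaneous <- function(model,
                                  ordering = seq_along(model@channelLabels)) {
  stopifnot(is(model, "MvarModel"))
  m <- length(model@channelLabels)
  if (!identical(sort(as.integer(ordering)), seq_len(m)))
    stop("'ordering' must be a permutation of the channel indices")
  ev <- eigen(model@Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("residual covariance is not positive definite")
  P <- diag(m)[as.integer(ordering), , drop = FALSE]
  Sp <- P %*% model@Sigma %*% t(P)
  U <- chol(Sp)
  d <- diag(U)
  Lunit <- t(U) %*% diag(1 / d, m)
  Lo <- t(P) %*% Lunit %*% P
  Loinv <- solve(Lo)
  B0 <- diag(m) - Loinv
  diag(B0) <- 0  # unit diagonal of Lo^-1 by construction
  Anew <- lapply(model@A, function(Ak) Loinv %*% Ak)
  Dsig <- t(P) %*% diag(d^2, m) %*% P
  Dsig[abs(Dsig) < .Machine$double.eps^0.5 * max(abs(Dsig))] <- 0
  Dsig <- diag(diag(Dsig), m)
  new("MvarModel", order = model@order, A = Anew, B0 = B0, Sigma = Dsig,
      fs = model@fs, nSamples = model@nSamples,
      channelLabels = model@channelLabels,
      ordering = as.integer(ordering))
}

# Spectral transfer polynomial Abar(f) = (I - B0) - sum_k A_k exp(-i 2 pi f
# k / fs); complex array channels x channels x frequency.
transferPolynomial <- function(A, freqs, fs, B0 = NULL) {
  m <- nrow(A[[1L]])
  lag0 <- if (is.null(B0)) diag(m) else diag(m) - B0
  out <- array(0 + 0i, dim = c(m, m, length(freqs)))
  for (fi in seq_along(freqs)) {
    Ab <- lag0 + 0i
    for (k in seq_along(A))
      Ab <- Ab - A[[k]] * exp(-2i * pi * freqs[fi] * k / fs)
    out[, , fi] <- Ab
  }
  out
}

# Model-implied spectral matrix S(f) = H(f) Sigma H(f)^H with H = Abar^-1.
spectralMatrix <- function(model, freqs) {
  Ab <- transferPolynomial(model@A, freqs, model@fs, model@B0)
  m <- dim(Ab)[1L]
  S <- array(0 + 0i, dim = dim(Ab))
  for (fi in seq_along(freqs)) {
    H <- solve(Ab[, , fi])
    S[, , fi] <- H %*% model@Sigma %*% Conj(t(H))
  }
  S
}

#' Model-based coherency
#'
#' Complex coherency derived from the fitted MVAR coefficients via the
#' spectral factorization `S(f) = H(f) Sigma H(f)^H`:
#' `coherency_ij(f) = S_ij / sqrt(S_ii S_jj)`.
#'
#' @param model an [MvarModel-class].
#' @param freqs frequency grid in Hz.
#' @return a [CoherencyMatrix-class] (`nWindows = NA`).
#' @export
modelCoherency <- function(model, freqs = seq(0, 60, by = 0.5)) {
  S <- spectralMatrix(model, freqs)
  m <- dim(S)[1L]
  dg <- matrix(0, m, length(freqs))
  for (ch in seq_len(m)) dg[ch, ] <- Re(S[ch, ch, ])
  if (any(dg <= 0))
    stop("degenerate spectrum: non-positive diagonal power")
  pairs <- enumeratePairs(m, directed = FALSE)
  vals <- matrix(0 + 0i, nrow(pairs), length(freqs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    vals[r, ] <- S[i, j, ] / sqrt(dg[i, ] * dg[j, ])
  }
  mag <- Mod(vals)
  over <- which(mag > 1)
  if (length(over)) vals[over] <- vals[over] / mag[over]
  new("CoherencyMatrix", values = vals, freqs = freqs, pairs = pairs,
      nWindows = NA_real_, channelLabels = model@channelLabels)
}

#' Partial directed coherence from MVAR coefficients
#'
#' Evaluates complex PDC `pi_ij(f) = Abar_ij(f) / sqrt(sum_k |Abar_kj(f)|^2)`
#' (coupling from source column j to target row i). The column normalization
#' includes the diagonal term, so squared PDC sums to exactly 1 over targets
#' for every source and frequency.
#'
#' @param A list of lag coefficient matrices.
#' @param freqs frequency grid in Hz.
#' @param fs sampling rate the lags refer to, in Hz.
#' @param B0 optional instantaneous coefficient matrix (extended model).
#' @param channelLabels optional labels.
#' @return list of class `PdcArray`: `values` is a complex
#'   target x source x frequency array, plus `freqs` and `channelLabels`.
#' @export
pdcFromCoefficients <- function(A, freqs, fs, B0 = NULL,
                                channelLabels = NULL) {
  Ab <- transferPolynomial(A, freqs, fs, B0)
  m <- dim(Ab)[1L]
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(m))
  for (fi in seq_along(freqs)) {
    nrm <- sqrt(colSums(Mod(Ab[, , fi, drop = FALSE][, , 1L])^2))
    if (any(nrm == 0))
      stop("undefined PDC normalization: all-zero column in Abar(f)")
    Ab[, , fi] <- sweep(Ab[, , fi], 2L, nrm, `/`)
  }
  structure(list(values = Ab, freqs = freqs, channelLabels = channelLabels),
            class = "PdcArray")
}

#' @rdname pdcFromCoefficients
#' @param model an [MvarModel-class]; uses its (possibly re-expressed)
#'   lagged coefficients, and its instantaneous matrix when present.
#' @export
modelPdc <- function(model, freqs = seq(0, 60, by = 0.5)) {
  stopifnot(is(model, "MvarModel"))
  pdcFromCoefficients(model@A, freqs, model@fs, model@B0,
                      model@channelLabels)
}

#' Pool complex PDC across trials
#'
#' Averages trial-wise complex PDC and squares the magnitude, giving pooled
#' directed connectivity spectra over the 90 ordered channel pairs (for 10
#' channels). Pooled column sums over targets are at most 1 by convexity.
#'
#' @param pdcs list of `PdcArray` objects on identical frequency grids.
#' @param subject,condition identifiers stored in the result.
#' @return a directed [ConnectivitySpectra-class].
#' @export
poolPdc <- function(pdcs, subject = NA_character_,
                    condition = NA_character_) {
  stopifnot(length(pdcs) >= 1L)
  f0 <- pdcs[[1L]]$freqs
  for (p in pdcs)
    if (!isTRUE(all.equal(p$freqs, f0)))
      stop("PDC arrays must share the frequency grid")
  acc <- Reduce(`+`, lapply(pdcs, `[[`, "values")) / length(pdcs)
  m <- dim(acc)[1L]
  pairs <- enumeratePairs(m, directed = TRUE)
  vals <- matrix(0, nrow(pairs), length(f0))
  for (r in seq_len(nrow(pairs)))
    vals[r, ] <- Mod(acc[pairs[r, "to"], pairs[r, "from"], ])^2
  new("ConnectivitySpectra", values = vals, freqs = f0, pairs = pairs,
      directed = TRUE, subject = as.character(subject),
      condition = as.character(condition),
      channelLabels = pdcs[[1L]]$channelLabels)
}
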