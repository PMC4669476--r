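#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Multichannel EMG study container
#'
#' Holds a set of EMG trials (one channel x sample matrix per trial) together
#' with the sampling rate, channel labels, a trial annotation table
#' (subject / condition / trial identifiers) and a provenance block (generator
#' specification and seed, or acquisition notes). All trials of a study share
#' the sampling rate and channel set.
#'
#' The `branch` slot records what the sample values are: `"raw"` for raw EMG,
#' `"envelope"` for nonnegative amplitude envelopes (coherence branch), and
#' `"mvar"` for band-passed, downsampled, z-scored envelopes (MVAR branch).
#'
#' @slot trials list of numeric matrices, channels x samples, one per trial.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of unique muscle labels (row order).
#' @slot info data.frame with columns `subject`, `condition`, `trial`,
#'   one row per element of `trials`.
#' @slot branch one of `"raw"`, `"envelope"`, `"mvar"`.
#' @slot provenance list; generator spec and master seed, or free-form notes.
#' @export
setClass("EmgStudy",
  representation(
    trials = "list",
    fs = "numeric",
    channelLabels = "character",
    info = "data.frame",
    branch = "character",
    provenance = "list"
  ),
  prototype(branch = "raw", provenance = list())
)

setValidity("EmgStudy", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (nrow(object@info) != length(object@trials))
    msg <- c(msg, "'info' must have one row per trial")
  need <- c("subject", "condition", "trial")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "'info' must have subject, condition, trial columns")
  nch <- length(object@channelLabels)
  for (i in seq_along(object@trials)) {
    tr <- object@trials[[i]]
    if (!is.matrix(tr) || !is.numeric(tr)) {
      msg <- c(msg, sprintf("trial %d is not a numeric matrix", i))
      break
    }
    if (nrow(tr) != nch) {
      msg <- c(msg, sprintf("trial %d has %d channels, expected %d",
                            i, nrow(tr), nch))
      break
    }
  }
  if (!object@branch %in% c("raw", "envelope", "mvar"))
    msg <- c(msg, "branch must be 'raw', 'envelope' or 'mvar'")
  if (length(msg)) msg else TRUE
})

#' Trial-level complex coherency
#'
#' Complex-valued coherency for every unordered channel pair on a common
#' frequency grid, as estimated from one trial (Welch averaging over tapered
#' windows) or derived from a fitted MVAR model (`nWindows = NA`).
#'
#' @slot values complex matrix, pairs (i < j, row-major) x frequency.
#' @slot freqs frequency grid in Hz, strictly increasing.
#' @slot pairs two-column integer matrix of (i, j) channel indices per row.
#' @slot nWindows number of Welch windows averaged (NA for model-based).
#' @slot channelLabels channel labels the pair indices refer to.
#' @export
setClass("CoherencyMatrix",
  representation(
    values = "matrix",
    freqs = "numeric",
    pairs = "matrix",
    nWindows = "numeric",
    channelLabels = "character"
  )
)

setValidity("CoherencyMatrix", function(object) {
  msg <- character()
  if (!is.complex(object@values))
    msg <- c(msg, "'values' must be a complex matrix")
  if (nrow(object@values) != nrow(object@pairs))
    msg <- c(msg, "one row of 'values' per pair")
  if (ncol(object@values) != length(object@freqs))
    msg <- c(msg, "one column of 'values' per frequency")
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "'freqs' must be strictly increasing")
  if (length(object@values) &&
      any(Mod(object@values) > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "coherency magnitude exceeds 1 + 1e-9")
  if (length(msg)) msg else TRUE
})

#' Pooled connectivity spectra
#'
#' Nonnegative pair x frequency connectivity values for one subject and
#' condition: trial-pooled magnitude-squared coherence (undirected) or pooled
#' squared partial directed coherence (directed). Undirected rows are indexed
#' by unordered pairs i < j; directed rows by ordered (source, target) pairs.
#'
#' @slot values nonnegative numeric matrix, pairs x frequency.
#' @slot freqs frequency grid in Hz.
#' @slot pairs two-column integer matrix; columns `from` (source) and `to`
#'   (target); `from < to` when undirected.
#' @slot directed logical flag.
#' @slot subject,condition identifiers.
#' @slot channelLabels channel labels.
#' @export
setClass("ConnectivitySpectra",
  representation(
    values = "matrix",
    freqs = "numeric",
    pairs = "matrix",
    directed = "logical",
    subject = "character",
    condition = "character",
    channelLabels = "character"
  )
)

setValidity("ConnectivitySpectra", function(object) {
  msg <- character()
  if (any(object@values < 0))
    msg <- c(msg, "connectivity values must be nonnegative")
  if (!object@directed && length(object@values) &&
      any(object@values > 1 + 1e-9))
    msg <- c(msg, "undirected coherence values must be <= 1")
  if (nrow(object@values) != nrow(object@pairs))
    msg <- c(msg, "one row of 'values' per pair")
  if (ncol(object@values) != length(object@freqs))
    msg <- c(msg, "one column of 'values' per frequency")
  if (length(msg)) msg else TRUE
})

#' Fitted multivariate autoregressive model
#'
#' Strictly causal MVAR model fitted by ordinary least squares, optionally
#' extended with an instantaneous (lag-zero) coefficient matrix identified by
#' Cholesky factorization of the residual covariance under a stated channel
#' ordering.
#'
#' @slot order model order p (number of lags).
#' @slot A list of p channel x channel lag coefficient matrices.
#' @slot B0 instantaneous coefficient matrix (zero diagonal) or NULL.
#' @slot Sigma residual covariance (diagonal when B0 is present).
#' @slot fs sampling rate of the modelled signals in Hz.
#' @slot nSamples number of regression samples used in the fit.
#' @slot channelLabels channel labels.
#' @slot ordering integer causal ordering used for B0 identification.
#' @export
setClass("MvarModel",
  representation(
    order = "integer",
    A = "list",
    B0 = "matrixOrNULL",
    Sigma = "matrix",
    fs = "numeric",
    nSamples = "integer",
    channelLabels = "character",
    ordering = "integer"
  ),
  prototype(B0 = NULL, ordering = integer())
)

setValidity("MvarModel", function(object) {
  msg <- character()
  m <- length(object@channelLabels)
  if (length(object@A) != object@order)
    msg <- c(msg, "need one coefficient matrix per lag")
  for (Ak in object@A)
    if (!all(dim(Ak) == c(m, m))) {
      msg <- c(msg, "coefficient matrices must be channels x channels")
      break
    }
  if (!all(dim(object@Sigma) == c(m, m)))
    msg <- c(msg, "'Sigma' must be channels x channels")
  if (max(abs(object@Sigma - t(object@Sigma))) > 1e-10)
    msg <- c(msg, "'Sigma' must be symmetric (tol 1e-10)")
  if (length(msg)) msg else TRUE
})

#' Nonnegative factorization of stacked connectivity spectra
#'
#' Result of alternating-least-squares NMF of a frequency x observation
#' spectra stack: `W` holds the frequency basis vectors (spectral signatures),
#' `H` the nonnegative loadings that become edge weights of per-component
#' muscle networks. `index` maps the columns of `H` back to
#' (pair, condition, subject) triples.
#'
#' @slot W frequency x K nonnegative basis matrix.
#' @slot H K x observation nonnegative loading matrix.
#' @slot freqs frequency grid of the rows of `W`, in Hz.
#' @slot index data.frame with columns `from`, `to`, `condition`, `subject`,
#'   one row per column of `H`.
#' @slot directed logical flag inherited from the input spectra.
#' @slot channelLabels channel labels.
#' @slot error final Frobenius reconstruction error of the best restart.
#' @slot errorTrace per-iteration error of the best restart (non-increasing).
#' @slot iterations iterations used by the best restart.
#' @slot restart index of the best restart.
#' @export
setClass("NmfFactorization",
  representation(
    W = "matrix",
    H = "matrix",
    freqs = "numeric",
    index = "data.frame",
    directed = "logical",
    channelLabels = "character",
    error = "numeric",
    errorTrace = "numeric",
    iterations = "integer",
    restart = "integer"
  )
)

setValidity("NmfFactorization", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "factors must be nonnegative")
  if (ncol(object@W) != nrow(object@H))
    msg <- c(msg, "inner dimensions of W and H must agree")
  if (nrow(object@W) != length(object@freqs))
    msg <- c(msg, "one row of W per frequency")
  if (nrow(object@index) != ncol(object@H))
    msg <- c(msg, "one index row per loading column")
  if (length(object@errorTrace) > 1 &&
      any(diff(object@errorTrace) > 1e-9 * object@errorTrace[1]))
    msg <- c(msg, "error trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Weighted muscle network
#'
#' Weighted adjacency over muscles for one NMF component, condition and
#' subject. Undirected networks are symmetric with zero diagonal; directed
#' networks store weight `adjacency[target, source]`... edges run column
#' (source) to row (target) to match the partial-directed-coherence
#' convention.
#'
#' @slot adjacency nonnegative muscle x muscle weight matrix, zero diagonal.
#' @slot directed logical flag.
#' @slot component component label (e.g. ordinal after peak-frequency sort).
#' @slot condition,subject identifiers.
#' @slot channelLabels node labels.
#' @export
setClass("MuscleNetwork",
  representation(
    adjacency = "matrix",
    directed = "logical",
    component = "character",
    condition = "character",
    subject = "character",
    channelLabels = "character"
  ),
  prototype(component = NA_character_, condition = NA_character_,
            subject = NA_character_)
)

setValidity("MuscleNetwork", function(object) {
  msg <- character()
  A <- object@adjacency
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (any(A < 0)) msg <- c(msg, "weights must be nonnegative")
  if (any(diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
  if (!object@directed && length(A) && max(abs(A - t(A))) > 1e-12)
    msg <- c(msg, "undirected network must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Muscle synergy set
#'
#' Nonnegative synergy basis vectors (muscle weight profiles) and activation
#' time courses extracted from EMG envelopes of one subject and condition,
#' together with the cumulative PCA variance-explained curve used to choose
#' the number of synergies.
#'
#' @slot basis muscles x n_synergies nonnegative weights, unit-norm columns.
#' @slot activations n_synergies x time nonnegative activations.
#' @slot varianceExplained cumulative PCA variance curve (ends at 1).
#' @slot subject,condition identifiers.
#' @slot channelLabels muscle labels.
#' @export
setClass("SynergySet",
  representation(
    basis = "matrix",
    activations = "matrix",
    varianceExplained = "numeric",
    subject = "character",
    condition = "character",
    channelLabels = "character"
  )
)

setValidity("SynergySet", function(object) {
  msg <- character()
  if (any(object@basis < 0) || any(object@activations < 0))
    msg <- c(msg, "basis and activations must be nonnegative")
  if (ncol(object@basis) != nrow(object@activations))
    msg <- c(msg, "number of synergies must agree between basis/activations")
  v <- object@varianceExplained
  if (length(v) && (any(diff(v) < -1e-10) || abs(v[length(v)] - 1) > 1e-8))
    msg <- c(msg, "variance-explained curve must be non-decreasing, ending at 1")
  if (length(msg)) msg else TRUE
})
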