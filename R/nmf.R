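#' Stack connectivity spectra for unmixing
#'
#' Restricts each spectra object to the analysis band (0-60 Hz by default)
#' and stacks them into a single nonnegative frequency x observation matrix,
#' one column per (pair, condition, subject) triple. Columns are ordered
#' subject-major, then condition, then pair, each in order of first
#' appearance, so the stacking is deterministic and reversible.
#'
#' @param spectra list of [ConnectivitySpectra-class], one per
#'   (subject, condition), all on the same grid and pair map.
#' @param band frequency band in Hz retained for the factorization.
#' @return list of class `SpectraStack` with `V` (frequency x observation),
#'   `freqs`, `index` (data.frame from/to/condition/subject), `directed`,
#'   `channelLabels`.
#' @export
stackSpectra <- function(spectra, band = c(0, 60)) {
  stopifnot(length(spectra) >= 1L)
  s0 <- spectra[[1L]]
  for (s in spectra) {
    stopifnot(is(s, "ConnectivitySpectra"))
    if (!isTRUE(all.equal(s@freqs, s0@freqs)) ||
        !identical(s@pairs, s0@pairs) || s@directed != s0@directed)
      stop("spectra must share grid, pair map and directedness")
    if (any(s@values < 0)) stop("connectivity values must be nonnegative")
  }
  key <- vapply(spectra, function(s) paste(s@subject, s@condition, sep = "\r"),
                "")
  if (anyDuplicated(key))
    stop("duplicate (subject, condition) spectra in the input")
  subjects <- unique(vapply(spectra, function(s) s@subject, ""))
  conditions <- unique(vapply(spectra, function(s) s@condition, ""))
  ord <- order(match(vapply(spectra, function(s) s@subject, ""), subjects),
               match(vapply(spectra, function(s) s@condition, ""), conditions))
  spectra <- spectra[ord]
  keep <- s0@freqs >= band[1L] & s0@freqs <= band[2L]
  V <- do.call(cbind, lapply(spectra, function(s)
    t(s@values[, keep, drop = FALSE])))
  np <- nrow(s0@pairs)
  index <- do.call(rbind, lapply(spectra, function(s)
    data.frame(from = s@pairs[, "from"], to = s@pairs[, "to"],
               condition = rep(s@condition, np),
               subject = rep(s@subject, np), stringsAsFactors = FALSE)))
  structure(list(V = V, freqs = s0@freqs[keep], index = index,
                 directed = s0@directed, channelLabels = s0@channelLabels),
            class = "SpectraStack")
}

#' Unstack a spectra stack
#'
#' Inverse of [stackSpectra()]: recovers one [ConnectivitySpectra-class] per
#' (subject, condition), band-restricted.
#'
#' @param stack a `SpectraStack`.
#' @return list of [ConnectivitySpectra-class].
#' @export
unstackSpectra <- function(stack) {
  stopifnot(inherits(stack, "SpectraStack"))
  grp <- paste(stack$index$subject, stack$index$condition, sep = "\r")
  lapply(unique(grp), function(g) {
    cols <- which(grp == g)
    new("ConnectivitySpectra",
        values = t(stack$V[, cols, drop = FALSE]),
        freqs = stack$freqs,
        pairs = cbind(from = stack$index$from[cols],
                      to = stack$index$to[cols]),
        directed = stack$directed,
        subject = stack$index$subject[cols[1L]],
        condition = stack$index$condition[cols[1L]],
        channelLabels = stack$channelLabels)
  })
}

# One projected-ALS run from a seeded random nonnegative initialization.
# Each half-step solves the unconstrained least-squares problem and clips
# negatives to zero; iteration stops when the Frobenius error stops
# improving (last improving iterate kept, so the trace is non-increasing)
# or its relative change drops below tol.
alsRun <- function(V, k, tol, maxIter) {
  solveClip <- function(G, B) {
    X <- tryCatch(solve(G, B), error = function(e) {
      solve(G + diag(1e-10 * (1 + mean(diag(G))), nrow(G)), B)
    })
    X[X < 0] <- 0
    X
  }
  nr <- nrow(V); nc <- ncol(V)
  scale <- sqrt(mean(V) / k)
  W <- matrix(stats::runif(nr * k), nr, k) * scale
  H <- matrix(stats::runif(k * nc), k, nc) * scale
  err <- norm(V - W %*% H, "F")
  trace <- err
  for (it in seq_len(maxIter)) {
    Hn <- solveClip(crossprod(W), t(W) %*% V)
    Wn <- t(solveClip(tcrossprod(Hn), Hn %*% t(V)))
    errn <- norm(V - Wn %*% Hn, "F")
    if (errn > err) break
    W <- Wn; H <- Hn
    improved <- err - errn
    err <- errn
    trace <- c(trace, err)
    if (improved < tol * max(err, .Machine$double.eps)) break
  }
  list(W = W, H = H, error = err, trace = trace,
       iterations = length(trace) - 1L)
}

#' Non-negative matrix factorization by alternating least squares
#'
#' Factorizes a nonnegative matrix `V` (frequency x observation) into
#' `W %*% H` with `W >= 0`, `H >= 0` by projected alternating least squares:
#' each half-step is an exact least-squares solve with negative entries
#' clipped to zero. The best of `nRestarts` seeded random restarts (by final
#' Frobenius error) is returned; results are deterministic given `seed`.
#'
#' @param V nonnegative numeric matrix.
#' @param k number of components, `k <= min(dim(V))`.
#' @param tol relative Frobenius-error change below which a run stops.
#' @param maxIter iteration cap per restart.
#' @param nRestarts number of random restarts.
#' @param seed master integer seed.
#' @return list with `W`, `H`, `error`, `errorTrace`, `iterations`,
#'   `restart` (index of the winning restart).
#' @export
nmfAls <- function(V, k = 4, tol = 1e-6, maxIter = 500, nRestarts = 10,
                   seed = 1L) {
  stopifnot(is.matrix(V))
  if (any(V < 0)) stop("V must be nonnegative")
  if (all(V == 0)) stop("degenerate input: V is all zero")
  if (k > min(dim(V)))
    stop("k must not exceed the smaller dimension of V")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(subSeed(seed, r))
    run <- alsRun(V, k, tol, maxIter)
    if (is.null(best) || run$error < best$error) {
      best <- run
      best$restart <- r
    }
  }
  names(best)[names(best) == "trace"] <- "errorTrace"
  best
}

#' Unmix stacked spectra into frequency components
#'
#' Runs [nmfAls()] on a `SpectraStack` and wraps the result as an
#' [NmfFactorization-class] carrying the frequency grid and observation
#' index. Apply [orderAndNormalize()] to fix the scale and component order.
#'
#' @param stack a `SpectraStack` from [stackSpectra()].
#' @inheritParams nmfAls
#' @return an [NmfFactorization-class].
#' @export
unmixSpectra <- function(stack, k = 4, tol = 1e-6, maxIter = 500,
                         nRestarts = 10, seed = 1L) {
  stopifnot(inherits(stack, "SpectraStack"))
  fit <- nmfAls(stack$V, k = k, tol = tol, maxIter = maxIter,
                nRestarts = nRestarts, seed = seed)
  new("NmfFactorization", W = fit$W, H = fit$H, freqs = stack$freqs,
      index = stack$index, directed = stack$directed,
      channelLabels = stack$channelLabels, error = fit$error,
      errorTrace = fit$errorTrace, iterations = fit$iterations,
      restart = fit$restart)
}

#' Reconstruction error as a function of K
#'
#' Scree report: relative Frobenius reconstruction error of [nmfAls()] for a
#' range of component counts, to support choosing K.
#'
#' @param stack a `SpectraStack`.
#' @param ks integer vector of component counts to evaluate.
#' @inheritParams nmfAls
#' @return data.frame with columns `k` and `relativeError`.
#' @export
nmfScree <- function(stack, ks = 1:8, tol = 1e-6, maxIter = 500,
                     nRestarts = 5, seed = 1L) {
  nv <- norm(stack$V, "F")
  data.frame(k = ks, relativeError = vapply(ks, function(k)
    nmfAls(stack$V, k, tol, maxIter, nRestarts, seed)$error / nv, 0))
}

#' Normalize and order NMF components
#'
#' Scales each basis column of `W` to unit Euclidean norm with the
#' compensating inverse scale on the corresponding row of `H` (the product
#' `W %*% H` is unchanged to within round-off), drops all-zero components
#' with a warning, and sorts components by ascending basis peak frequency.
#'
#' @param fac an [NmfFactorization-class].
#' @return the normalized, ordered [NmfFactorization-class].
#' @export
orderAndNormalize <- function(fac) {
  stopifnot(is(fac, "NmfFactorization"))
  nrm <- sqrt(colSums(fac@W^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero component(s) dropped")
    fac@W <- fac@W[, !zero, drop = FALSE]
    fac@H <- fac@H[!zero, , drop = FALSE]
    nrm <- nrm[!zero]
  }
  W <- sweep(fac@W, 2L, nrm, `/`)
  H <- sweep(fac@H, 1L, nrm, `*`)
  peak <- fac@freqs[apply(W, 2L, which.max)]
  ord <- order(peak)
  fac@W <- W[, ord, drop = FALSE]
  fac@H <- H[ord, , drop = FALSE]
  validObject(fac)
  fac
}

#' Per-component weighted muscle networks
#'
#' Reshapes the NMF loadings into one weighted adjacency matrix per
#' (component, condition, subject): symmetric fill for undirected loadings,
#' ordered (source -> target) fill for directed ones; the diagonal is zero.
#'
#' @param fac an [NmfFactorization-class] (typically after
#'   [orderAndNormalize()]).
#' @return list of [MuscleNetwork-class] objects, component-major.
#' @export
componentNetworks <- function(fac) {
  stopifnot(is(fac, "NmfFactorization"))
  m <- length(fac@channelLabels)
  grp <- paste(fac@index$subject, fac@index$condition, sep = "\r")
  groups <- unique(grp)
  out <- list()
  for (k in seq_len(nrow(fac@H))) {
    for (g in groups) {
      cols <- which(grp == g)
      A <- matrix(0, m, m, dimnames = list(fac@channelLabels,
                                           fac@channelLabels))
      for (cc in cols) {
        i <- fac@index$to[cc]; j <- fac@index$from[cc]
        w <- fac@H[k, cc]
        A[i, j] <- w
        if (!fac@directed) A[j, i] <- w
      }
      out[[length(out) + 1L]] <-
        new("MuscleNetwork", adjacency = A, directed = fac@directed,
            component = sprintf("comp%d", k),
            condition = fac@index$condition[cols[1L]],
            subject = fac@index$subject[cols[1L]],
            channelLabels = fac@channelLabels)
    }
  }
  out
}
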