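#' Accessors for musclenet objects
#'
#' Small accessor generics that expose the slots of the core containers
#' without touching `@` directly: channel labels, sampling rate, trial
#' matrices and annotations, frequency grids, connectivity values, pair
#' indices, model coefficients, NMF factors and network adjacency.
#'
#' @param x a musclenet object.
#' @param i trial index (for `trialData`).
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("channelLabels", "EmgStudy", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "CoherencyMatrix", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "ConnectivitySpectra", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "MvarModel", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "NmfFactorization", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "MuscleNetwork", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "SynergySet", function(x) x@channelLabels)

#' @rdname accessors
setMethod("samplingRate", "EmgStudy", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "MvarModel", function(x) x@fs)

#' @rdname accessors
setMethod("trialData", "EmgStudy", function(x, i) x@trials[[i]])
#' @rdname accessors
setMethod("trialInfo", "EmgStudy", function(x) x@info)
#' @rdname accessors
setMethod("nTrials", "EmgStudy", function(x) length(x@trials))

#' @rdname accessors
setMethod("frequencies", "CoherencyMatrix", function(x) x@freqs)
#' @rdname accessors
setMethod("frequencies", "ConnectivitySpectra", function(x) x@freqs)
#' @rdname accessors
setMethod("frequencies", "NmfFactorization", function(x) x@freqs)

#' @rdname accessors
setMethod("connectivityValues", "CoherencyMatrix", function(x) x@values)
#' @rdname accessors
setMethod("connectivityValues", "ConnectivitySpectra", function(x) x@values)

#' @rdname accessors
setMethod("pairIndex", "CoherencyMatrix", function(x) x@pairs)
#' @rdname accessors
setMethod("pairIndex", "ConnectivitySpectra", function(x) x@pairs)

#' @rdname accessors
setMethod("isDirected", "ConnectivitySpectra", function(x) x@directed)
#' @rdname accessors
setMethod("isDirected", "NmfFactorization", function(x) x@directed)
#' @rdname accessors
setMethod("isDirected", "MuscleNetwork", function(x) x@directed)

#' @rdname accessors
setMethod("modelOrder", "MvarModel", function(x) x@order)
#' @rdname accessors
setMethod("lagMatrices", "MvarModel", function(x) x@A)
#' @rdname accessors
setMethod("residCov", "MvarModel", function(x) x@Sigma)

#' @rdname accessors
setMethod("basisMatrix", "NmfFactorization", function(x) x@W)
#' @rdname accessors
setMethod("basisMatrix", "SynergySet", function(x) x@basis)
#' @rdname accessors
setMethod("loadingsMatrix", "NmfFactorization", function(x) x@H)
#' @rdname accessors
setMethod("activations", "SynergySet", function(x) x@activations)

#' @rdname accessors
setMethod("adjacencyMatrix", "MuscleNetwork", function(x) x@adjacency)

setMethod("show", "EmgStudy", function(object) {
  cat(sprintf("EmgStudy: %d trial(s), %d channel(s) @ %g Hz [%s]\n",
              length(object@trials), length(object@channelLabels),
              object@fs, object@branch))
  cat(sprintf("  subjects: %s\n",
              paste(unique(object@info$subject), collapse = ", ")))
  cat(sprintf("  conditions: %s\n",
              paste(unique(object@info$condition), collapse = ", ")))
  invisible(object)
})

setMethod("show", "CoherencyMatrix", function(object) {
  cat(sprintf("CoherencyMatrix: %d pair(s) x %d frequencies (%g-%g Hz), %s\n",
              nrow(object@values), length(object@freqs),
              min(object@freqs), max(object@freqs),
              if (is.na(object@nWindows)) "model-based"
              else sprintf("%d Welch windows", object@nWindows)))
  invisible(object)
})

setMethod("show", "ConnectivitySpectra", function(object) {
  cat(sprintf("ConnectivitySpectra (%s): %d pair(s) x %d frequencies\n",
              if (object@directed) "directed" else "undirected",
              nrow(object@values), length(object@freqs)))
  cat(sprintf("  subject %s, condition %s\n", object@subject,
              object@condition))
  invisible(object)
})

setMethod("show", "MvarModel", function(object) {
  cat(sprintf("MvarModel: order %d, %d channel(s) @ %g Hz%s\n",
              object@order, length(object@channelLabels), object@fs,
              if (is.null(object@B0)) "" else " (extended, instantaneous)"))
  invisible(object)
})

setMethod("show", "NmfFactorization", function(object) {
  cat(sprintf(
    "NmfFactorization: K = %d, %d frequencies x %d observations\n",
    ncol(object@W), nrow(object@W), ncol(object@H)))
  cat(sprintf("  reconstruction error %.4g after %d iteration(s)\n",
              object@error, object@iterations))
  invisible(object)
})

setMethod("show", "MuscleNetwork", function(object) {
  cat(sprintf("MuscleNetwork (%s): %d nodes, component %s, %s / %s\n",
              if (object@directed) "directed" else "undirected",
              nrow(object@adjacency), object@component, object@subject,
              object@condition))
  invisible(object)
})

setMethod("show", "SynergySet", function(object) {
  cat(sprintf("SynergySet: %d synergies x %d muscles (%s / %s)\n",
              ncol(object@basis), nrow(object@basis), object@subject,
              object@condition))
  invisible(object)
})
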