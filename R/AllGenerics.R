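#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("trialData", function(x, i) standardGeneric("trialData"))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("connectivityValues", function(x) standardGeneric("connectivityValues"))

#' @rdname accessors
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))

#' @rdname accessors
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' @rdname accessors
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' @rdname accessors
#' @export
setGeneric("lagMatrices", function(x) standardGeneric("lagMatrices"))

#' @rdname accessors
#' @export
setGeneric("residCov", function(x) standardGeneric("residCov"))

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname accessors
#' @export
setGeneric("loadingsMatrix", function(x) standardGeneric("loadingsMatrix"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("activations", function(x) standardGeneric("activations"))
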