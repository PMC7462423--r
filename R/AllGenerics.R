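#' @rdname SpikeRecording-class
#' @param x,object A package object.
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname SpikeRecording-class
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname SpikeRecording-class
#' @param id Integer neuron id (omit for all neurons).
#' @export
setGeneric("spikeTimes", function(x, id) standardGeneric("spikeTimes"))

#' @rdname SpikeRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname SpikeRecording-class
#' @export
setGeneric("recordingLabel", function(x) standardGeneric("recordingLabel"))

#' @rdname BinnedRaster-class
#' @param x A package object.
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname BinnedRaster-class
#' @export
setGeneric("binWidthMs", function(x) standardGeneric("binWidthMs"))

#' @rdname BinnedRaster-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname EffectiveNetwork-class
#' @param x A package object.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname EffectiveNetwork-class
#' @export
setGeneric("timescale", function(x) standardGeneric("timescale"))

#' Extract the information terms of a PIDResult as a named vector
#'
#' @param x A [PIDResult-class].
#' @return Named numeric vector with elements `te_j`, `te_k`, `mvte`,
#'   `redundancy`, `synergy`, `unique_j`, `unique_k`, `receiver_entropy`.
#' @export
setGeneric("pidTerms", function(x) standardGeneric("pidTerms"))

#' @rdname PIDResult-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
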