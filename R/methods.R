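#' @rdname SpikeRecording-class
#' @export
setMethod("nNeurons", "SpikeRecording", function(x) length(x@spikes))

#' @rdname SpikeRecording-class
#' @export
setMethod("neuronIds", "SpikeRecording", function(x) as.integer(names(x@spikes)))

#' @rdname SpikeRecording-class
#' @export
setMethod("spikeTimes", "SpikeRecording", function(x, id) {
  if (missing(id)) return(x@spikes)
  key <- as.character(id)
  if (!key %in% names(x@spikes)) stop("unknown neuron id: ", id)
  x@spikes[[key]]
})

#' @rdname SpikeRecording-class
#' @export
setMethod("duration", "SpikeRecording", function(x) x@duration)

#' @rdname SpikeRecording-class
#' @export
setMethod("recordingLabel", "SpikeRecording", function(x) x@label)

setMethod("show", "SpikeRecording", function(object) {
  n <- nNeurons(object)
  total <- sum(lengths(object@spikes))
  cat("SpikeRecording:", n, "neurons,", total, "spikes,",
      format(object@duration), "s\n")
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
  if (n > 0 && object@duration > 0) {
    r <- lengths(object@spikes) / object@duration
    cat(sprintf("  firing rates (Hz): median %.3g, range [%.3g, %.3g]\n",
                stats::median(r), min(r), max(r)))
  }
})

#' @rdname BinnedRaster-class
#' @export
setMethod("states", "BinnedRaster", function(x) x@states)

#' @rdname BinnedRaster-class
#' @export
setMethod("binWidthMs", "BinnedRaster", function(x) x@binWidthMs)

#' @rdname BinnedRaster-class
#' @export
setMethod("nBins", "BinnedRaster", function(x) ncol(x@states))

#' @rdname BinnedRaster-class
#' @export
setMethod("nNeurons", "BinnedRaster", function(x) nrow(x@states))

#' @rdname BinnedRaster-class
#' @export
setMethod("neuronIds", "BinnedRaster", function(x) as.integer(rownames(x@states)))

setMethod("show", "BinnedRaster", function(object) {
  cat("BinnedRaster:", nrow(object@states), "neurons x", ncol(object@states),
      "bins @", object@binWidthMs, "ms\n")
  if (length(object@states))
    cat(sprintf("  mean occupancy: %.4f\n", mean(object@states)))
})

#' @rdname EffectiveNetwork-class
#' @export
setMethod("edges", "EffectiveNetwork", function(x) x@edges)

#' @rdname EffectiveNetwork-class
#' @export
setMethod("timescale", "EffectiveNetwork", function(x) x@timescale)

#' @rdname EffectiveNetwork-class
#' @export
setMethod("nNeurons", "EffectiveNetwork", function(x) length(x@neuronIds))

#' @rdname EffectiveNetwork-class
#' @export
setMethod("neuronIds", "EffectiveNetwork", function(x) x@neuronIds)

setMethod("show", "EffectiveNetwork", function(object) {
  ts <- object@timescale
  cat("EffectiveNetwork:", nrow(object@edges), "significant edges among",
      length(object@neuronIds), "neurons\n")
  cat(sprintf("  timescale: %s ms bins, delays %d..%d (alpha = %g, %g jitters)\n",
              format(ts$bin_width_ms), min(ts$delays), max(ts$delays),
              object@alpha, object@nJitter))
})

#' @rdname pidTerms
#' @export
setMethod("pidTerms", "PIDResult", function(x) {
  c(te_j = x@teJ, te_k = x@teK, mvte = x@mvte,
    redundancy = x@redundancy, synergy = x@synergy,
    unique_j = x@uniqueJ, unique_k = x@uniqueK,
    receiver_entropy = x@receiverEntropy)
})

#' @rdname PIDResult-class
#' @export
setMethod("isNormalized", "PIDResult", function(x) x@normalized)

setMethod("show", "PIDResult", function(object) {
  unit <- if (object@normalized) "proportion of receiver entropy" else "bits"
  cat("PIDResult (", unit, ")\n", sep = "")
  v <- pidTerms(object)
  for (nm in names(v)) cat(sprintf("  %-16s %s\n", nm, format(v[[nm]], digits = 6)))
})
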