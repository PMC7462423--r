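#' @import methods
NULL

#' SpikeRecording: a multineuron spike-train recording
#'
#' Container for one recording: per-neuron sorted spike times (seconds),
#' the recording duration, and a free-text label. Neuron identifiers are
#' integers; spike times are validated to lie in `[0, duration]` and to be
#' sorted nondecreasing within each neuron.
#'
#' @slot spikes Named list of numeric vectors; names are neuron ids, each
#'   vector the sorted spike times of that neuron in seconds.
#' @slot duration Numeric scalar, recording length in seconds.
#' @slot label Character scalar, free-text provenance.
#'
#' @seealso [SpikeRecording()], [readSpikeTable()], [binSpikes()]
#' @export
setClass("SpikeRecording",
  representation(spikes = "list", duration = "numeric", label = "character"),
  prototype(spikes = list(), duration = 0, label = "")
)

setValidity("SpikeRecording", function(object) {
  msgs <- character()
  ids <- names(object@spikes)
  if (length(object@spikes) > 0L) {
    if (is.null(ids) || anyNA(suppressWarnings(as.integer(ids))))
      msgs <- c(msgs, "spikes must be named by integer neuron ids")
    if (anyDuplicated(ids))
      msgs <- c(msgs, "neuron ids must be unique")
  }
  if (length(object@duration) != 1L || is.na(object@duration) || object@duration < 0)
    msgs <- c(msgs, "duration must be a single nonnegative number")
  for (i in seq_along(object@spikes)) {
    st <- object@spikes[[i]]
    if (!is.numeric(st))
      msgs <- c(msgs, sprintf("spike times of neuron %s are not numeric", ids[i]))
    else {
      if (is.unsorted(st))
        msgs <- c(msgs, sprintf("spike times of neuron %s are not sorted", ids[i]))
      if (length(st) && (min(st) < 0 || max(st) > object@duration))
        msgs <- c(msgs, sprintf("spike times of neuron %s outside [0, duration]", ids[i]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpikeRecording
#'
#' @param spikes Named list of numeric spike-time vectors (seconds); names are
#'   integer neuron ids. Times are sorted internally.
#' @param duration Recording length in seconds. Defaults to the maximum spike
#'   time rounded up to the next whole second.
#' @param label Free-text provenance label.
#' @return A [SpikeRecording-class] object.
#' @examples
#' rec <- SpikeRecording(list(`1` = c(0.1, 0.25), `2` = 0.2), duration = 1)
#' nNeurons(rec)
#' @export
SpikeRecording <- function(spikes = list(), duration = NULL, label = "") {
  spikes <- lapply(spikes, function(x) sort(as.numeric(x)))
  if (length(spikes) && is.null(names(spikes)))
    names(spikes) <- as.character(seq_along(spikes))
  if (is.null(duration)) {
    mx <- if (length(spikes)) suppressWarnings(max(0, unlist(spikes, use.names = FALSE))) else 0
    duration <- ceiling(mx)
  }
  new("SpikeRecording", spikes = spikes, duration = as.numeric(duration),
      label = as.character(label))
}

#' BinnedRaster: binary spike occupancy at a fixed bin width
#'
#' Per-neuron binary state sequences: state 1 iff at least one spike fell in
#' the half-open bin `[k*w, (k+1)*w)`. Stored as an integer matrix with one
#' row per neuron.
#'
#' @slot states Integer matrix (neurons x bins) of 0/1 occupancy states.
#' @slot binWidthMs Numeric scalar, bin width in milliseconds.
#'
#' @seealso [binSpikes()]
#' @export
setClass("BinnedRaster",
  representation(states = "matrix", binWidthMs = "numeric")
)

setValidity("BinnedRaster", function(object) {
  msgs <- character()
  if (!is.integer(object@states))
    msgs <- c(msgs, "states must be an integer matrix")
  else if (length(object@states) && any(object@states < 0L))
    msgs <- c(msgs, "states must be nonnegative integers")
  if (length(object@binWidthMs) != 1L || object@binWidthMs <= 0)
    msgs <- c(msgs, "binWidthMs must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' PIDResult: triad-level information decomposition
#'
#' Holds the bivariate transfer entropies, the multivariate transfer entropy
#' (mvTE), and the partial-information terms (redundancy, synergy, unique
#' contributions) for one sender-pair/receiver triad, in bits, or — after
#' [normalizePID()] — as proportions of the receiver's single-bin entropy.
#'
#' @slot teJ,teK Bivariate transfer entropy from each sender (bits).
#' @slot mvte Multivariate transfer entropy from both senders jointly (bits).
#' @slot redundancy,synergy,uniqueJ,uniqueK Partial information terms (bits).
#' @slot receiverEntropy Single-bin entropy of the receiver (bits); set by
#'   [normalizePID()].
#' @slot normalized Logical flag: `TRUE` once terms have been divided by the
#'   receiver entropy.
#'
#' @seealso [pidDecompose()], [normalizePID()], [pidTerms()]
#' @export
setClass("PIDResult",
  representation(teJ = "numeric", teK = "numeric", mvte = "numeric",
                 redundancy = "numeric", synergy = "numeric",
                 uniqueJ = "numeric", uniqueK = "numeric",
                 receiverEntropy = "numeric", normalized = "logical"),
  prototype(receiverEntropy = NA_real_, normalized = FALSE)
)

setValidity("PIDResult", function(object) {
  tol <- 1e-10
  v <- c(object@teJ, object@teK, object@mvte, object@redundancy,
         object@synergy, object@uniqueJ, object@uniqueK)
  if (anyNA(v)) return(TRUE)  # flagged-missing results are allowed
  msgs <- character()
  if (any(v < -tol))
    msgs <- c(msgs, "information terms must be >= -1e-10")
  if (abs(object@uniqueJ + object@uniqueK + object@redundancy +
          object@synergy - object@mvte) > 1e-8)
    msgs <- c(msgs, "PID terms must sum to mvte")
  if (length(msgs)) msgs else TRUE
})

#' EffectiveNetwork: significant transfer-entropy connections at one timescale
#'
#' Directed weighted graph of connections whose transfer entropy exceeded the
#' jitter-surrogate null at the chosen significance level. Edge weights carry
#' both raw TE (bits) and TE normalized by the receiving neuron's entropy.
#'
#' @slot edges data.frame with columns `source`, `target`, `te`, `te_norm`,
#'   `peak_delay` (bins), `p_value`.
#' @slot timescale List describing the analysis timescale (see
#'   [standardTimescales()]): at least `bin_width_ms` and `delays`.
#' @slot neuronIds Integer vector of all neuron ids tested.
#' @slot alpha Significance level used for edge inclusion.
#' @slot nJitter Number of jitter surrogates per tested pair.
#'
#' @seealso [buildEffectiveNetwork()], [enumerateTriads()]
#' @export
setClass("EffectiveNetwork",
  representation(edges = "data.frame", timescale = "list",
                 neuronIds = "integer", alpha = "numeric", nJitter = "numeric")
)

setValidity("EffectiveNetwork", function(object) {
  msgs <- character()
  ed <- object@edges
  need <- c("source", "target", "te", "te_norm", "peak_delay", "p_value")
  if (!all(need %in% names(ed)))
    msgs <- c(msgs, paste("edges must have columns:", paste(need, collapse = ", ")))
  else if (nrow(ed)) {
    if (any(ed$source == ed$target)) msgs <- c(msgs, "self-edges are not allowed")
    if (any(ed$p_value >= object@alpha)) msgs <- c(msgs, "all stored edges must be significant")
    ok <- !is.na(ed$te_norm)
    if (any(ed$te_norm[ok] < 0 | ed$te_norm[ok] > 1 + 1e-6))
      msgs <- c(msgs, "normalized TE must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})
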