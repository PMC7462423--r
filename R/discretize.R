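#' The ten standard analysis timescales
#'
#' Each timescale is a bin width `w` (ms) plus a set of source delays
#' (in bins), so that the source is evaluated over lags spanning
#' `w * min(delays)` to `w * max(delays)` ms. The first timescale uses
#' delays 1..60 at 0.05-ms bins (span 0.05-3 ms); the remaining nine use
#' delays 1..4, giving spans 1.6-6.4 up to 750-3000 ms. Timescales 1-3 are
#' the synaptic group, 7-9 the extrasynaptic group; the nominal center (ms)
#' is a conventional label, not a midpoint.
#'
#' @return data.frame with one row per timescale: `id`, `bin_width_ms`,
#'   `max_delay`, `span_min_ms`, `span_max_ms`, `center_ms`, `group`.
#' @seealso [getTimescale()] for a single timescale in the list form taken
#'   by [timescaleTE()] and [buildEffectiveNetwork()].
#' @examples
#' standardTimescales()
#' @export
standardTimescales <- function() {
  w <- c(0.05, 1.6, 3.5, 7.5, 16.15, 34.8, 75, 161.6, 348.1, 750)
  md <- c(60L, rep(4L, 9))
  data.frame(
    id = 1:10,
    bin_width_ms = w,
    max_delay = md,
    span_min_ms = w,
    span_max_ms = w * md,
    center_ms = c(3, 5, 11, 23, 48, 104, 225, 485, 1044, 2250),
    group = c(rep("synaptic", 3), rep("mid", 3), rep("extrasynaptic", 3), "longest"),
    stringsAsFactors = FALSE
  )
}

#' Fetch one standard timescale as a spec list
#'
#' @param id Timescale id, 1-10.
#' @return List with fields `id`, `bin_width_ms`, `delays` (integer vector),
#'   `span_ms` (length-2), `center_ms`, `group`.
#' @export
getTimescale <- function(id) {
  tab <- standardTimescales()
  if (!id %in% tab$id) stop("timescale id must be in 1..10")
  row <- tab[tab$id == id, ]
  list(id = row$id, bin_width_ms = row$bin_width_ms,
       delays = seq_len(row$max_delay),
       span_ms = c(row$span_min_ms, row$span_max_ms),
       center_ms = row$center_ms, group = row$group)
}

# spike times (s) -> 0-based bin indices kept inside [0, nBins)
.binIndices <- function(times, binWidthS, nBins) {
  idx <- floor(times / binWidthS)
  idx[idx >= 0 & idx < nBins]
}

#' Discretize a recording into a binned raster
#'
#' Bins are half-open `[k*w, (k+1)*w)` with 0-based indices; a spike exactly
#' at `duration` is dropped. The number of bins is
#' `floor(duration / bin width)`. By default the state is binary occupancy
#' (1 iff at least one spike fell in the bin); with `binarize = FALSE` the
#' state is the spike count, which downstream information measures treat as
#' a larger discrete alphabet.
#'
#' @param recording A [SpikeRecording-class].
#' @param binWidthMs Bin width in milliseconds (> 0).
#' @param binarize Logical; clip counts to 0/1 (default `TRUE`).
#' @return A [BinnedRaster-class] with one row per neuron.
#' @examples
#' rec <- SpikeRecording(list(`1` = c(0.2, 0.9)), duration = 1)
#' states(binSpikes(rec, 500))
#' @export
binSpikes <- function(recording, binWidthMs, binarize = TRUE) {
  stopifnot(is(recording, "SpikeRecording"))
  if (!is.numeric(binWidthMs) || length(binWidthMs) != 1L || binWidthMs <= 0)
    stop("bin width must be a single positive number (ms)")
  w <- binWidthMs / 1000
  nb <- floor(recording@duration / w)
  if (nb < 1) stop("duration must be at least one bin width")
  mat <- matrix(0L, nrow = nNeurons(recording), ncol = nb,
                dimnames = list(names(recording@spikes), NULL))
  for (i in seq_len(nrow(mat))) {
    idx <- .binIndices(recording@spikes[[i]], w, nb)
    if (length(idx)) {
      cnt <- tabulate(idx + 1L, nbins = nb)
      mat[i, ] <- if (binarize) as.integer(cnt > 0L) else as.integer(cnt)
    }
  }
  new("BinnedRaster", states = mat, binWidthMs = as.numeric(binWidthMs))
}
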