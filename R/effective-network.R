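# Jitter-surrogate significance testing of delayed transfer entropy and
# assembly of per-timescale effective networks. Only the source train is
# jittered; the target and its history structure are preserved. The
# half-window defaults to 5x the timescale's maximum lag, wide enough to
# destroy within-window spike timing while preserving slow rate structure.

#' Jitter surrogate of a spike train
#'
#' Displaces each spike independently by uniform(-halfWindow, +halfWindow),
#' clips to `[0, duration]`, and re-sorts. Spike count is preserved.
#'
#' @param times Numeric spike times (seconds).
#' @param halfWindowMs Half-width of the jitter window in milliseconds.
#' @param duration Recording duration in seconds (for clipping).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Jittered, sorted spike-time vector.
#' @export
jitterSurrogate <- function(times, halfWindowMs, duration, seed = NULL) {
  if (halfWindowMs <= 0) stop("halfWindowMs must be positive")
  jit <- function() {
    hw <- halfWindowMs / 1000
    sort(pmin(pmax(times + stats::runif(length(times), -hw, hw), 0), duration))
  }
  if (is.null(seed)) jit() else withr::with_seed(seed, jit())
}

# target alignment cache for fast repeated TE over one target; all delays
# share the alignment at the largest delay, as in timescaleTE()
.teTargetPrep <- function(target, delays) {
  nt <- max(target) + 1L
  n <- length(target)
  dmax <- max(delays)
  if (n <= dmax + 1L) stop("raster too short for the requested delays")
  t <- (dmax + 1L):n
  list(delays = as.integer(delays), dmax = dmax, n = n, nt = nt,
       base = target[t] + nt * target[t - 1L],
       hAligned = .h(tabulate(target[t] + 1L, nbins = nt) / length(t)))
}

# max-over-delays TE of a binary source against a prepped target
.teMaxPrepped <- function(srcStates, prep) {
  best <- -Inf; bestDelay <- NA_integer_
  nt2 <- prep$nt * prep$nt
  for (d in prep$delays) {
    j <- srcStates[(prep$dmax - d + 1L):(prep$n - d)]
    counts <- tabulate(prep$base + nt2 * j + 1L, nbins = nt2 * 2L)
    te <- teFromTable(array(counts / sum(counts), dim = c(prep$nt, prep$nt, 2L)))
    if (te > best) { best <- te; bestDelay <- d }
  }
  list(te = best, peak_delay = bestDelay)
}

#' Significance of one directed connection against a jitter null
#'
#' The observed statistic is the delay-maximized transfer entropy
#' ([timescaleTE()]). The null distribution is the same statistic for
#' `nJitter` jitter surrogates of the source (target fixed). The p-value
#' uses the add-one rank estimator `p = (1 + #\{null >= observed\}) /
#' (1 + nJitter)`, so it is never zero; `nJitter` must be at least
#' `1/alpha - 1` for the requested level to be attainable.
#'
#' @param sourceTimes Spike times of the candidate source (seconds).
#' @param targetStates Binned integer states of the target at the
#'   timescale's bin width (see [binSpikes()]).
#' @param duration Recording duration in seconds.
#' @param spec Timescale spec list (see [getTimescale()]).
#' @param nJitter Number of surrogates (default 5000).
#' @param alpha Significance level (default 0.001).
#' @param halfWindowMs Jitter half-window; default `5 * bin_width_ms *
#'   max(delays)`.
#' @param seed Optional integer seed.
#' @return List with `te`, `peak_delay`, `p_value`, `significant`.
#' @export
connectionSignificance <- function(sourceTimes, targetStates, duration, spec,
                                   nJitter = 5000, alpha = 0.001,
                                   halfWindowMs = NULL, seed = NULL) {
  if (nJitter < 1 / alpha - 1)
    stop("configuration error: nJitter must be >= 1/alpha - 1 for p-values ",
         "resolvable at alpha = ", alpha)
  if (is.null(halfWindowMs)) halfWindowMs <- 5 * spec$bin_width_ms * max(spec$delays)
  targetStates <- .asStates(targetStates, "targetStates")
  run <- function() {
    delays <- as.integer(spec$delays)
    w <- spec$bin_width_ms / 1000
    nb <- length(targetStates)
    binSrc <- function(times) {
      idx <- .binIndices(times, w, nb)
      as.integer(tabulate(idx + 1L, nbins = nb) > 0L)
    }
    prep <- .teTargetPrep(targetStates, delays)
    obs <- .teMaxPrepped(binSrc(sourceTimes), prep)
    null <- vapply(seq_len(nJitter), function(i) {
      .teMaxPrepped(binSrc(jitterSurrogate(sourceTimes, halfWindowMs, duration)),
                    prep)$te
    }, numeric(1))
    p <- (1 + sum(null >= obs$te)) / (1 + nJitter)
    list(te = obs$te, peak_delay = obs$peak_delay, p_value = p,
         significant = p < alpha)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Build the effective network of significant TE connections
#'
#' Tests every ordered neuron pair at one timescale with
#' [connectionSignificance()] and keeps the significant directed edges.
#' Edge TE is also normalized by the receiving neuron's single-bin entropy
#' (`te_norm`, the proportion of the receiver's capacity accounted for).
#' Deterministic given `seed`.
#'
#' @param recording A [SpikeRecording-class] with at least 3 neurons.
#' @param spec Timescale spec list (see [getTimescale()]).
#' @param nJitter,alpha,halfWindowMs As in [connectionSignificance()].
#' @param seed Integer seed for the surrogate RNG.
#' @param binarize Passed to [binSpikes()].
#' @return An [EffectiveNetwork-class].
#' @export
buildEffectiveNetwork <- function(recording, spec, nJitter = 5000, alpha = 0.001,
                                  halfWindowMs = NULL, seed = NULL,
                                  binarize = TRUE) {
  stopifnot(is(recording, "SpikeRecording"))
  if (nNeurons(recording) < 3L) stop("at least 3 neurons are required")
  if (nJitter < 1 / alpha - 1)
    stop("configuration error: nJitter must be >= 1/alpha - 1")
  raster <- binSpikes(recording, spec$bin_width_ms, binarize = binarize)
  ids <- neuronIds(recording)
  st <- states(raster)
  # receiver entropy on the delay-aligned sample, so te / entropy <= 1 exactly
  hRec <- apply(st, 1L, function(v) .teTargetPrep(v, spec$delays)$hAligned)
  run <- function() {
    rows <- list()
    for (ti in seq_along(ids)) {
      if (hRec[ti] == 0) next  # constant receiver: TE undefined/zero
      tgt <- st[ti, ]
      for (si in seq_along(ids)) {
        if (si == ti) next
        if (length(recording@spikes[[si]]) == 0L) next
        res <- connectionSignificance(recording@spikes[[si]], tgt,
                                      recording@duration, spec,
                                      nJitter = nJitter, alpha = alpha,
                                      halfWindowMs = halfWindowMs, seed = NULL)
        if (res$significant) {
          rows[[length(rows) + 1L]] <- data.frame(
            source = ids[si], target = ids[ti], te = res$te,
            te_norm = res$te / hRec[ti], peak_delay = res$peak_delay,
            p_value = res$p_value)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(source = integer(), target = integer(), te = numeric(),
                    te_norm = numeric(), peak_delay = integer(),
                    p_value = numeric())
  }
  ed <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  new("EffectiveNetwork", edges = ed, timescale = spec,
      neuronIds = as.integer(ids), alpha = alpha, nJitter = as.numeric(nJitter))
}

#' Enumerate sender-pair/receiver triads of an effective network
#'
#' A triad is an unordered pair of distinct neurons `{J, K}` that both have
#' significant connections onto a common receiver `I`. Every receiver with
#' in-degree `d` yields `choose(d, 2)` triads.
#'
#' @param network An [EffectiveNetwork-class].
#' @return data.frame with columns `sender_j`, `sender_k` (`sender_j <
#'   sender_k`), `receiver`.
#' @export
enumerateTriads <- function(network) {
  stopifnot(is(network, "EffectiveNetwork"))
  ed <- edges(network)
  out <- list()
  for (rec in unique(ed$target)) {
    senders <- sort(unique(ed$source[ed$target == rec]))
    senders <- senders[senders != rec]
    if (length(senders) < 2L) next
    pairs <- utils::combn(senders, 2L)
    out[[length(out) + 1L]] <- data.frame(
      sender_j = pairs[1L, ], sender_k = pairs[2L, ], receiver = rec)
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[order(res$receiver, res$sender_j, res$sender_k), , drop = FALSE]
  } else {
    data.frame(sender_j = integer(), sender_k = integer(), receiver = integer())
  }
}

#' Evaluate information terms for every triad of a network
#'
#' For each triad: the zero-lag normalized mutual information between the
#' senders (at the network's bin width) and the partial information
#' decomposition of the two senders' transfer entropy at the edges' peak
#' delays, normalized by the receiver's entropy when `normalized = TRUE`.
#' Triads whose sender MI or receiver entropy is undefined (constant
#' sequences) are flagged; flagged rows are excluded from downstream
#' statistics.
#'
#' @param recording The [SpikeRecording-class] the network was built from.
#' @param network An [EffectiveNetwork-class].
#' @param triads Optional triad data.frame (default [enumerateTriads()]).
#' @param mode PID redundancy mode, `"imin"` or `"lower_bound"`.
#' @param normalized Divide information terms by receiver entropy
#'   (default `TRUE`).
#' @param binarize Passed to [binSpikes()].
#' @return data.frame with one row per triad: ids, `mi_norm`, `te_j`,
#'   `te_k`, `mvte`, `redundancy`, `synergy`, `unique_j`, `unique_k`,
#'   `receiver_entropy`, `flagged`.
#' @export
evaluateTriads <- function(recording, network, triads = NULL,
                           mode = c("imin", "lower_bound"),
                           normalized = TRUE, binarize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(recording, "SpikeRecording"), is(network, "EffectiveNetwork"))
  if (is.null(triads)) triads <- enumerateTriads(network)
  spec <- timescale(network)
  raster <- binSpikes(recording, spec$bin_width_ms, binarize = binarize)
  st <- states(raster)
  key <- as.character(neuronIds(raster))
  ed <- edges(network)
  delayOf <- function(s, t) {
    hit <- ed$peak_delay[ed$source == s & ed$target == t]
    if (length(hit) != 1L) stop("triad edge (", s, " -> ", t, ") not in network")
    hit
  }
  n <- nrow(triads)
  cols <- c("mi_norm", "te_j", "te_k", "mvte", "redundancy", "synergy",
            "unique_j", "unique_k", "receiver_entropy")
  vals <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  flagged <- logical(n)
  for (r in seq_len(n)) {
    j <- st[match(as.character(triads$sender_j[r]), key), ]
    k <- st[match(as.character(triads$sender_k[r]), key), ]
    i <- st[match(as.character(triads$receiver[r]), key), ]
    mi <- mutualInformationNorm(j, k)
    dJ <- delayOf(triads$sender_j[r], triads$receiver[r])
    dK <- delayOf(triads$sender_k[r], triads$receiver[r])
    pid <- pidDecompose(j, k, i, delayJ = dJ, delayK = dK, mode = mode)
    if (normalized) {
      # receiver entropy on the same delay-aligned sample as the PID terms
      pid <- normalizePID(pid, receiver = i[(max(dJ, dK) + 1L):length(i)])
    }
    tm <- pidTerms(pid)
    vals[r, ] <- c(mi, tm[["te_j"]], tm[["te_k"]], tm[["mvte"]],
                   tm[["redundancy"]], tm[["synergy"]], tm[["unique_j"]],
                   tm[["unique_k"]], tm[["receiver_entropy"]])
    flagged[r] <- is.na(mi) || anyNA(tm[1:7])
  }
  cbind(triads, as.data.frame(vals), flagged = flagged)
}

#' Export an effective network as text
#'
#' @param network An [EffectiveNetwork-class].
#' @param path Output file path.
#' @param format `"edgelist"` (tab-delimited: source, target, te,
#'   normalized_te, peak_delay_bins, p_value) or `"graphml"` (via igraph).
#' @return Invisibly, `path`.
#' @export
exportNetwork <- function(network, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(network, "EffectiveNetwork"))
  ed <- edges(network)
  if (format == "edgelist") {
    out <- data.frame(source = ed$source, target = ed$target, te = ed$te,
                      normalized_te = ed$te_norm,
                      peak_delay_bins = ed$peak_delay, p_value = ed$p_value)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                       vertices = data.frame(name = network@neuronIds))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
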