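# Synthetic spike-train generators with known ground truth. Sender pairs
# share a tunable fraction of a common Poisson source (superposition
# construction: marginal rates are preserved exactly and the c = 0 / c = 1
# limits are analytically independent / identical). Receivers implement a
# boolean gate on binarized sender states at the generator's internal bin
# width, decoupled from the analysis bin width.

.rpoisTrain <- function(rate, duration) {
  n <- stats::rpois(1L, rate * duration)
  sort(stats::runif(n, 0, duration))
}

#' Generate a sender-pair/receiver triad recording
#'
#' Senders J and K are Poisson trains with rates `rateJ`, `rateK`, of which
#' a fraction `commonDrive` (of the smaller rate) is drawn from a shared
#' Poisson source, so sender-sender correlation rises monotonically from
#' independent (`commonDrive = 0`) to maximal (`commonDrive = 1`). The
#' receiver fires `lagMs` after every internal bin whose binarized sender
#' states satisfy the gate (`copy_j`, `or`, `and`, `xor`), with probability
#' `reliability`, superposed on background Poisson noise.
#'
#' @param rateJ,rateK Sender rates (spikes/s).
#' @param commonDrive Shared-source fraction in `[0, 1]`.
#' @param gate One of `"copy_j"`, `"or"`, `"and"`, `"xor"`.
#' @param lagMs Transmission lag (ms).
#' @param reliability Transmission probability in `[0, 1]`.
#' @param backgroundRate Receiver background rate (spikes/s).
#' @param duration Recording length (seconds).
#' @param seed Integer seed (deterministic output).
#' @param genBinMs Internal gate bin width (ms, default 1).
#' @return A [SpikeRecording-class] with neurons 1 (J), 2 (K), 3 (receiver).
#' @examples
#' rec <- generateTriad(rateJ = 10, rateK = 10, commonDrive = 0.5,
#'                      gate = "or", duration = 10, seed = 1)
#' rateSummary(rec)
#' @export
generateTriad <- function(rateJ = 10, rateK = 10, commonDrive = 0,
                          gate = c("copy_j", "or", "and", "xor"),
                          lagMs = 2, reliability = 1, backgroundRate = 0,
                          duration = 60, seed = 1, genBinMs = 1) {
  gate <- match.arg(gate)
  if (commonDrive < 0 || commonDrive > 1) stop("commonDrive must be in [0, 1]")
  if (reliability < 0 || reliability > 1) stop("reliability must be in [0, 1]")
  if (any(c(rateJ, rateK, backgroundRate) < 0)) stop("rates must be nonnegative")
  sharedRate <- commonDrive * min(rateJ, rateK)
  if (sharedRate > rateJ + 1e-12 || sharedRate > rateK + 1e-12)
    stop("shared fraction exceeds a sender's target rate")
  withr::with_seed(seed, {
    shared <- .rpoisTrain(sharedRate, duration)
    trainJ <- sort(c(shared, .rpoisTrain(rateJ - sharedRate, duration)))
    trainK <- sort(c(shared, .rpoisTrain(rateK - sharedRate, duration)))
    w <- genBinMs / 1000
    nb <- floor(duration / w)
    occ <- function(times) {
      idx <- .binIndices(times, w, nb)
      tabulate(idx + 1L, nbins = nb) > 0L
    }
    gJ <- occ(trainJ)
    gK <- occ(trainK)
    g <- switch(gate,
                copy_j = gJ,
                or = gJ | gK,
                and = gJ & gK,
                xor = xor(gJ, gK))
    hit <- which(g)
    if (length(hit) && reliability < 1)
      hit <- hit[stats::runif(length(hit)) < reliability]
    gateTimes <- (hit - 1L) * w + w / 2 + lagMs / 1000
    gateTimes <- gateTimes[gateTimes < duration]
    receiver <- sort(c(gateTimes, .rpoisTrain(backgroundRate, duration)))
    SpikeRecording(list(`1` = trainJ, `2` = trainK, `3` = receiver),
                   duration = duration,
                   label = sprintf("synthetic triad (%s gate, c = %g)", gate,
                                   commonDrive))
  })
}

#' Generate a synthetic network recording with planted connections
#'
#' Baseline activity is independent Poisson with rates sampled from a
#' lognormal distribution (as observed in cortical cultures). Each planted
#' directed connection adds, for every source spike and with probability
#' `reliability`, a target spike at a fixed per-connection lag, implementing
#' lagged excitatory drive. The returned ground-truth edge list supports
#' recovery tests.
#'
#' @param nNeurons Number of neurons (>= 3).
#' @param rateMeanLog,rateSdLog Lognormal firing-rate parameters (log
#'   spikes/s); defaults give a median of 2 spikes/s.
#' @param pConnect Directed connection probability (ignored when `nEdges`
#'   is given).
#' @param nEdges Optional exact number of planted directed edges.
#' @param lagRangeMs Length-2 range of per-connection lags (ms).
#' @param reliability Per-spike transmission probability.
#' @param duration Recording length (seconds).
#' @param seed Integer seed.
#' @return List with `recording` ([SpikeRecording-class]) and `edges`
#'   (data.frame `source`, `target`, `lag_ms`, `reliability`).
#' @export
generateNetwork <- function(nNeurons = 30, rateMeanLog = log(2),
                            rateSdLog = 0.5, pConnect = 0.02, nEdges = NULL,
                            lagRangeMs = c(2, 6), reliability = 0.8,
                            duration = 60, seed = 1) {
  if (nNeurons < 3L) stop("nNeurons must be at least 3")
  withr::with_seed(seed, {
    rates <- stats::rlnorm(nNeurons, rateMeanLog, rateSdLog)
    spikes <- lapply(rates, .rpoisTrain, duration = duration)
    pairs <- expand.grid(source = seq_len(nNeurons), target = seq_len(nNeurons))
    pairs <- pairs[pairs$source != pairs$target, ]
    if (is.null(nEdges)) {
      keep <- stats::runif(nrow(pairs)) < pConnect
      ed <- pairs[keep, , drop = FALSE]
    } else {
      if (nEdges > nrow(pairs)) stop("nEdges exceeds the number of ordered pairs")
      ed <- pairs[sample.int(nrow(pairs), nEdges), , drop = FALSE]
    }
    ed$lag_ms <- if (nrow(ed)) stats::runif(nrow(ed), lagRangeMs[1], lagRangeMs[2]) else numeric()
    ed$reliability <- rep(reliability, nrow(ed))
    for (r in seq_len(nrow(ed))) {
      src <- spikes[[ed$source[r]]]
      keep <- stats::runif(length(src)) < ed$reliability[r]
      induced <- src[keep] + ed$lag_ms[r] / 1000
      induced <- induced[induced < duration]
      tgt <- ed$target[r]
      spikes[[tgt]] <- sort(c(spikes[[tgt]], induced))
    }
    names(spikes) <- as.character(seq_len(nNeurons))
    rownames(ed) <- NULL
    list(recording = SpikeRecording(spikes, duration = duration,
                                    label = "synthetic network"),
         edges = ed)
  })
}

#' Sample aligned state sequences from a joint table
#'
#' Draws `n` i.i.d. joint states from an explicit probability array and
#' returns one 0-based integer sequence per variable (dimension). The
#' empirical frequencies converge to the table as `n` grows, so plug-in
#' estimates computed from the sequences converge to the exact-table
#' values.
#'
#' @param p Probability array (any number of dimensions).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List of `length(dim(p))` integer vectors of length `n`.
#' @export
sampleFromTable <- function(p, n, seed = 1) {
  .checkDist(p)
  d <- dim(p)
  if (is.null(d)) d <- length(p)
  withr::with_seed(seed, {
    cells <- sample.int(length(p), n, replace = TRUE, prob = as.numeric(p))
    idx <- arrayInd(cells, .dim = d)
    lapply(seq_along(d), function(v) as.integer(idx[, v]) - 1L)
  })
}

#' Planted triad populations for regime-statistics validation
#'
#' Builds per-network triad tables in which sender mutual information is
#' drawn log-uniformly and synergy follows a known curve with lognormal
#' noise. In the default power-law mode, `synergy = mi^exponent * noise`,
#' so the log-log decile slope has a planted value. With `peakMi` set,
#' synergy instead follows a log-Gaussian bump peaking at `peakMi`, and
#' each network's MI range is randomly shifted (in log space) around the
#' peak so that the recovered saturation point varies continuously across
#' networks. Redundancy and mvTE are constructed to satisfy the accounting
#' identity with nonnegative unique terms (`redundancy = 0.3 * synergy`,
#' `unique = 0.1 * synergy` each, `mvte = 1.5 * synergy`).
#'
#' @param nNetworks,triadsPerNetwork Population size.
#' @param exponent Planted power-law exponent (power-law mode).
#' @param noiseSd SD of the lognormal noise (natural-log units).
#' @param seed Integer seed.
#' @param miRange Length-2 MI range for the log-uniform draw (power-law
#'   mode).
#' @param peakMi Optional planted saturation point (switches to bump mode).
#' @param peakWidthLog10 SD of the bump in log10(MI) units (default 0.5).
#' @return List of `nNetworks` triad data.frames (`mi_norm`, `synergy`,
#'   `redundancy`, `mvte`).
#' @export
plantedRegimePopulation <- function(nNetworks = 75, triadsPerNetwork = 800,
                                    exponent = 0.46, noiseSd = 0.2, seed = 1,
                                    miRange = c(1e-3, 1), peakMi = NULL,
                                    peakWidthLog10 = 0.5) {
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  if (!is.finite(exponent)) stop("exponent must be finite")
  withr::with_seed(seed, {
    lapply(seq_len(nNetworks), function(net) {
      if (is.null(peakMi)) {
        lmi <- stats::runif(triadsPerNetwork, log10(miRange[1]), log10(miRange[2]))
        mi <- 10^lmi
        syn <- mi^exponent * exp(stats::rnorm(triadsPerNetwork, 0, noiseSd))
      } else {
        shift <- stats::runif(1, -0.15, 0.15)
        lmi <- log10(peakMi) + stats::runif(triadsPerNetwork, -1, 1) + shift
        mi <- 10^lmi
        syn <- exp(-(lmi - log10(peakMi))^2 / (2 * peakWidthLog10^2)) *
          exp(stats::rnorm(triadsPerNetwork, 0, noiseSd))
      }
      data.frame(mi_norm = mi, synergy = syn, redundancy = 0.3 * syn,
                 mvte = 1.5 * syn)
    })
  })
}
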