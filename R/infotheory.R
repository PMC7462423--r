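# Core discrete information theory on plug-in (maximum-likelihood) joint
# distributions. All logs are base 2; 0*log(0) is treated as 0. Every
# sequence-based operation builds the empirical joint table and evaluates
# the same closed-form expression as its *FromTable counterpart, so the two
# routes agree exactly.

.asStates <- function(x, what = "sequence") {
  if (is.logical(x)) x <- as.integer(x)
  if (is(x, "BinnedRaster")) stop(what, " must be a single state vector, not a raster")
  if (!is.numeric(x) || length(x) == 0L)
    stop(what, " must be a nonempty integer state vector")
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0L)) stop(what, " must contain nonnegative integer states")
  x
}

# list of aligned 0-based integer vectors -> probability array
.empiricalArray <- function(vars) {
  nlev <- vapply(vars, function(v) max(v) + 1L, integer(1))
  code <- vars[[1L]]
  mult <- nlev[1L]
  if (length(vars) > 1L) {
    for (i in 2:length(vars)) {
      code <- code + vars[[i]] * mult
      mult <- mult * nlev[i]
    }
  }
  counts <- tabulate(code + 1L, nbins = mult)
  array(counts / length(code), dim = nlev)
}

.checkDist <- function(p, tol = 1e-8) {
  if (any(p < -1e-12)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > tol) stop("probabilities must sum to 1")
  invisible(p)
}

.h <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a discrete distribution
#'
#' @param p Probability vector (or array, flattened); must sum to 1.
#' @return Entropy in bits, with `0 * log 0 = 0`.
#' @examples
#' shannonEntropy(c(0.5, 0.5))
#' shannonEntropy(c(0.25, 0.75))
#' @export
shannonEntropy <- function(p) {
  .checkDist(p)
  .h(as.numeric(p))
}

#' Normalized mutual information from a joint table
#'
#' `MI(X;Y) / min(H(X), H(Y))`: the observed proportion of the maximum
#' mutual information the two marginals allow. Returns `NA` when either
#' marginal entropy is zero.
#'
#' @param p Matrix of joint probabilities `p(x, y)`.
#' @return Proportion in `[0, 1]`, or `NA_real_` if undefined.
#' @seealso [mutualInformationNorm()] for the sequence interface.
#' @export
miNormFromTable <- function(p) {
  .checkDist(p)
  if (!is.matrix(p)) stop("p must be a 2-d joint table")
  px <- rowSums(p)
  py <- colSums(p)
  hx <- .h(px)
  hy <- .h(py)
  if (hx == 0 || hy == 0) return(NA_real_)
  mi <- hx + hy - .h(as.numeric(p))
  mi / min(hx, hy)
}

#' Normalized mutual information between two state sequences
#'
#' Plug-in estimate of zero-lag mutual information between simultaneous
#' binned states, normalized by the smaller marginal entropy.
#'
#' @param x,y Equal-length integer state sequences.
#' @return Proportion in `[0, 1]`, `NA_real_` when a sequence is constant.
#' @examples
#' mutualInformationNorm(c(0, 1, 0, 1), c(0, 1, 0, 1))
#' @export
mutualInformationNorm <- function(x, y) {
  x <- .asStates(x, "x")
  y <- .asStates(y, "y")
  if (length(x) != length(y)) stop("x and y must have equal length")
  p <- .empiricalArray(list(x, y))
  miNormFromTable(matrix(as.numeric(p), nrow = dim(p)[1L]))
}

#' Transfer entropy from an explicit joint table
#'
#' Evaluates `TE(J -> I) = sum p(i_t, i_p, j) log2[ p(i_t | i_p, j) /
#' p(i_t | i_p) ]` over a 3-d joint table with dimensions ordered
#' (target future `i_t`, target past `i_p`, source past `j`).
#'
#' @param p 3-d probability array.
#' @return Transfer entropy in bits.
#' @export
teFromTable <- function(p) {
  .checkDist(p)
  d <- dim(p)
  if (length(d) != 3L) stop("p must be a 3-d joint table (i_t, i_p, j)")
  ni <- d[1L]; np <- d[2L]; nj <- d[3L]
  p_itip <- rowSums(p, dims = 2L)            # (i_t, i_p)
  p_ipj  <- colSums(p, dims = 1L)            # (i_p, j)
  p_ip   <- colSums(p_itip)                  # (i_p)
  pv <- as.numeric(p)
  b_itip <- rep(as.numeric(p_itip), times = nj)
  b_ipj  <- rep(as.numeric(p_ipj), each = ni)
  b_ip   <- rep(rep(p_ip, each = ni), times = nj)
  pos <- pv > 0
  sum(pv[pos] * log2(pv[pos] * b_ip[pos] / (b_ipj[pos] * b_itip[pos])))
}

#' Multivariate transfer entropy from an explicit joint table
#'
#' `TE({J,K} -> I)` over a 4-d joint table with dimensions ordered
#' (`i_t`, `i_p`, `j`, `k`).
#'
#' @param p 4-d probability array.
#' @return Multivariate transfer entropy in bits.
#' @export
mvteFromTable <- function(p) {
  .checkDist(p)
  d <- dim(p)
  if (length(d) != 4L) stop("p must be a 4-d joint table (i_t, i_p, j, k)")
  ni <- d[1L]; np <- d[2L]; njk <- d[3L] * d[4L]
  p_itip <- rowSums(p, dims = 2L)
  p_ipjk <- colSums(p, dims = 1L)
  p_ip   <- colSums(p_itip)
  pv <- as.numeric(p)
  b_itip <- rep(as.numeric(p_itip), times = njk)
  b_ipjk <- rep(as.numeric(p_ipjk), each = ni)
  b_ip   <- rep(rep(p_ip, each = ni), times = njk)
  pos <- pv > 0
  sum(pv[pos] * log2(pv[pos] * b_ip[pos] / (b_ipjk[pos] * b_itip[pos])))
}

# aligned (i_t, i_p, source-lagged...) slices for delay d; t = (d+1)..n
.alignLagged <- function(target, sources, delays) {
  n <- length(target)
  dmax <- max(delays, 1L)
  if (n <= dmax + 1L) stop("sequences too short for the requested delay")
  t <- (dmax + 1L):n
  out <- list(it = target[t], ip = target[t - 1L])
  for (s in seq_along(sources)) out[[s + 2L]] <- sources[[s]][t - delays[s]]
  out
}

#' Delayed transfer entropy between state sequences
#'
#' Plug-in transfer entropy from a source's state `delay` bins in the past
#' to the target's next state, conditioned on order-1 receiver history (the
#' single bin immediately preceding the future bin).
#'
#' @param source,target Equal-length integer state sequences.
#' @param delay Source lag in bins (positive integer).
#' @return Transfer entropy in bits.
#' @examples
#' j <- c(0, 1, 1, 0, 1, 0, 0, 1, 1, 0)
#' transferEntropy(j, c(0, j[-10]), delay = 1)
#' @export
transferEntropy <- function(source, target, delay = 1L) {
  source <- .asStates(source, "source")
  target <- .asStates(target, "target")
  if (length(source) != length(target)) stop("source and target must have equal length")
  delay <- as.integer(delay)
  if (delay < 1L) stop("delay must be a positive integer (bins)")
  al <- .alignLagged(target, list(source), delay)
  teFromTable(.empiricalArray(list(al$it, al$ip, al[[3L]])))
}

#' Transfer entropy maximized over a timescale's delay set
#'
#' Computes plug-in TE at every delay of a timescale and returns the
#' maximum together with the delay attaining it (ties broken toward the
#' smallest delay).
#'
#' @param source,target Equal-length integer state sequences binned at the
#'   timescale's bin width.
#' @param spec Timescale spec list (see [getTimescale()]); only `delays`
#'   is used.
#' @return List with `te` (bits), `peak_delay` (bins), and `te_by_delay`.
#' @export
timescaleTE <- function(source, target, spec) {
  source <- .asStates(source, "source")
  target <- .asStates(target, "target")
  if (length(source) != length(target)) stop("source and target must have equal length")
  delays <- as.integer(spec$delays)
  if (length(delays) == 0L || any(delays < 1L)) stop("spec$delays must be positive integers")
  # common alignment at the largest delay so every delay is scored on the
  # same future/history sample (and shares the receiver-entropy bound)
  n <- length(target)
  dmax <- max(delays)
  if (n <= dmax + 1L) stop("sequences too short for the requested delays")
  t <- (dmax + 1L):n
  it <- target[t]; ip <- target[t - 1L]
  tes <- vapply(delays, function(d) {
    teFromTable(.empiricalArray(list(it, ip, source[t - d])))
  }, numeric(1))
  best <- which.max(tes)  # first maximum = smallest delay on ties
  list(te = tes[best], peak_delay = delays[best], te_by_delay = tes)
}

#' Multivariate transfer entropy from two sources
#'
#' Plug-in `TE({J,K} -> I)` with each source taken at its own delay and
#' order-1 receiver history.
#'
#' @param sourceJ,sourceK,target Equal-length integer state sequences.
#' @param delayJ,delayK Source lags in bins.
#' @return Multivariate transfer entropy in bits.
#' @export
multivariateTE <- function(sourceJ, sourceK, target, delayJ = 1L, delayK = 1L) {
  sourceJ <- .asStates(sourceJ, "sourceJ")
  sourceK <- .asStates(sourceK, "sourceK")
  target <- .asStates(target, "target")
  if (length(sourceJ) != length(target) || length(sourceK) != length(target))
    stop("sequences must have equal length")
  dJ <- as.integer(delayJ); dK <- as.integer(delayK)
  if (dJ < 1L || dK < 1L) stop("delays must be positive integers")
  al <- .alignLagged(target, list(sourceJ, sourceK), c(dJ, dK))
  mvteFromTable(.empiricalArray(list(al$it, al$ip, al[[3L]], al[[4L]])))
}

#' Pearson correlation between binned state sequences
#'
#' Optional similarity measure for sender pairs, as an alternative to
#' [mutualInformationNorm()].
#'
#' @param x,y Equal-length numeric sequences.
#' @return Sample Pearson correlation, `NA_real_` if either variance is 0.
#' @export
pearsonSimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
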