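# Williams-Beer partial information decomposition of multivariate transfer
# entropy for two sources. Redundancy is I_min: the expectation, over the
# receiver's (future, past) states, of the smaller source-specific
# information. Because the specific information is a Kullback-Leibler
# divergence it is nonnegative, which makes redundancy <= min(TE_J, TE_K)
# and both unique terms nonnegative by construction.

# specific information of source S about i_t given i_p, per (i_t, i_p) cell:
# Ispec(i_t; S | i_p) = sum_s p(s | i_t, i_p) [log2 p(i_t | s, i_p) - log2 p(i_t | i_p)]
# p3: (i_t, i_p, s) joint table; returns (i_t, i_p) matrix (0 where p(i_t,i_p)=0)
.specificInformation <- function(p3) {
  d <- dim(p3)
  ni <- d[1L]; np <- d[2L]; ns <- d[3L]
  p_itip <- rowSums(p3, dims = 2L)           # (i_t, i_p)
  p_ips  <- colSums(p3, dims = 1L)           # (i_p, s)
  p_ip   <- colSums(p_itip)                  # (i_p)
  pv <- as.numeric(p3)
  b_itip <- rep(as.numeric(p_itip), times = ns)
  b_ips  <- rep(as.numeric(p_ips), each = ni)
  b_ip   <- rep(rep(p_ip, each = ni), times = ns)
  term <- numeric(length(pv))
  pos <- pv > 0
  # p3 * [log2 p(it|s,ip) - log2 p(it|ip)]; divide by p(it,ip) afterwards
  term[pos] <- pv[pos] * (log2(pv[pos] / b_ips[pos]) - log2(b_itip[pos] / b_ip[pos]))
  num <- rowSums(array(term, dim = d), dims = 2L)
  out <- matrix(0, ni, np)
  posip <- p_itip > 0
  out[posip] <- num[posip] / p_itip[posip]
  out
}

.newPID <- function(teJ, teK, mvte, red, syn, uJ, uK,
                    receiverEntropy = NA_real_, normalized = FALSE) {
  new("PIDResult", teJ = teJ, teK = teK, mvte = mvte, redundancy = red,
      synergy = syn, uniqueJ = uJ, uniqueK = uK,
      receiverEntropy = receiverEntropy, normalized = normalized)
}

#' Partial information decomposition from an explicit joint table
#'
#' Decomposes the multivariate transfer entropy of a 4-d joint table over
#' (receiver future `i_t`, receiver past `i_p`, source `j`, source `k`)
#' into redundancy, synergy, and unique source contributions. In mode
#' `"imin"` redundancy is the Williams-Beer expected minimum specific
#' information; synergy is then `mvte - te_j - te_k + redundancy`. In mode
#' `"lower_bound"` redundancy is the smallest value consistent with
#' nonnegative unique terms, `max(0, te_j + te_k - mvte)`, giving
#' `synergy = max(0, mvte - te_j - te_k)`.
#'
#' @param p 4-d probability array, dimensions `(i_t, i_p, j, k)`.
#' @param mode `"imin"` (default) or `"lower_bound"`.
#' @return A [PIDResult-class] in bits (not normalized).
#' @export
pidFromTable <- function(p, mode = c("imin", "lower_bound")) {
  mode <- match.arg(mode)
  .checkDist(p)
  d <- dim(p)
  if (length(d) != 4L) stop("p must be a 4-d joint table (i_t, i_p, j, k)")
  pj3 <- rowSums(p, dims = 3L)                          # (i_t, i_p, j)
  pk3 <- rowSums(aperm(p, c(1L, 2L, 4L, 3L)), dims = 3L) # (i_t, i_p, k)
  teJ <- teFromTable(pj3)
  teK <- teFromTable(pk3)
  mvte <- mvteFromTable(p)
  if (mode == "imin") {
    p_itip <- rowSums(p, dims = 2L)
    ispec <- pmin(.specificInformation(pj3), .specificInformation(pk3))
    red <- sum(p_itip * ispec)
    syn <- mvte - teJ - teK + red
  } else {
    red <- max(0, teJ + teK - mvte)
    syn <- max(0, mvte - teJ - teK)
  }
  uJ <- teJ - red
  uK <- teK - red
  tol <- 1e-10
  terms <- c(teJ, teK, mvte, red, syn, uJ, uK)
  if (any(terms < -tol))
    stop("internal consistency error: negative information term beyond tolerance")
  if (abs(uJ + uK + red + syn - mvte) > tol)
    stop("internal consistency error: PID terms do not sum to mvte")
  .newPID(teJ, teK, mvte, red, syn, uJ, uK)
}

#' Partial information decomposition of two sources' transfer entropy
#'
#' Builds the plug-in joint table of (receiver future, receiver past,
#' source J at `delayJ`, source K at `delayK`) from aligned state sequences
#' and decomposes it with [pidFromTable()]. All terms (including the
#' bivariate TEs) are evaluated on this one shared table, so the accounting
#' identity `unique_j + unique_k + redundancy + synergy = mvte` holds to
#' numerical precision.
#'
#' @param sourceJ,sourceK,target Equal-length integer state sequences.
#' @param delayJ,delayK Source lags in bins (each sender at its own peak
#'   delay from [timescaleTE()]).
#' @param mode `"imin"` (default) or `"lower_bound"`; see [pidFromTable()].
#' @return A [PIDResult-class] in bits.
#' @examples
#' set.seed(1)
#' j <- rbinom(3000, 1, 0.5); k <- rbinom(3000, 1, 0.5)
#' i <- c(0L, as.integer(xor(j, k))[-3000])  # XOR receiver at lag 1
#' pidDecompose(j, k, i, 1, 1)
#' @export
pidDecompose <- function(sourceJ, sourceK, target, delayJ = 1L, delayK = 1L,
                         mode = c("imin", "lower_bound")) {
  mode <- match.arg(mode)
  sourceJ <- .asStates(sourceJ, "sourceJ")
  sourceK <- .asStates(sourceK, "sourceK")
  target <- .asStates(target, "target")
  if (length(sourceJ) != length(target) || length(sourceK) != length(target))
    stop("sequences must have equal length")
  dJ <- as.integer(delayJ); dK <- as.integer(delayK)
  if (dJ < 1L || dK < 1L) stop("delays must be positive integers")
  al <- .alignLagged(target, list(sourceJ, sourceK), c(dJ, dK))
  pidFromTable(.empiricalArray(list(al$it, al$ip, al[[3L]], al[[4L]])), mode = mode)
}

#' Normalize a PIDResult by the receiver's entropy
#'
#' Divides every information term by the single-bin entropy of the
#' receiving neuron, expressing each as the proportion of the receiver's
#' capacity it accounts for. Normalizing twice is an error; a receiver
#' with zero entropy yields flagged missing values.
#'
#' @param result A [PIDResult-class] in bits.
#' @param receiver Integer state sequence of the receiver (the raster row),
#'   or a precomputed entropy in bits via `receiverEntropy`.
#' @param receiverEntropy Optional numeric entropy (bits) overriding
#'   `receiver`.
#' @return A normalized [PIDResult-class].
#' @export
normalizePID <- function(result, receiver = NULL, receiverEntropy = NULL) {
  stopifnot(is(result, "PIDResult"))
  if (result@normalized) stop("result is already normalized")
  if (is.null(receiverEntropy)) {
    if (is.null(receiver)) stop("provide receiver states or receiverEntropy")
    receiver <- .asStates(receiver, "receiver")
    receiverEntropy <- .h(tabulate(receiver + 1L, nbins = max(receiver) + 1L) /
                            length(receiver))
  }
  if (receiverEntropy <= 0) {
    return(.newPID(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                   NA_real_, NA_real_, receiverEntropy = 0, normalized = TRUE))
  }
  h <- receiverEntropy
  .newPID(result@teJ / h, result@teK / h, result@mvte / h,
          result@redundancy / h, result@synergy / h,
          result@uniqueJ / h, result@uniqueK / h,
          receiverEntropy = h, normalized = TRUE)
}
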