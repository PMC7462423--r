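# Regime statistics: triads are collapsed into deciles of sender mutual
# information per network, and all cross-network statistics (Spearman
# correlations, log-log regression slopes, bootstrap medians, Wilcoxon Z
# tests) operate on the decile medians.

.decileTerms <- c("mi_norm", "synergy", "redundancy", "mvte")

#' Collapse triads into deciles of sender mutual information
#'
#' Triads are sorted by `mi_norm` and split into 10 contiguous bins of
#' near-equal count (when the count is not divisible by 10, the extra
#' triads go to the lowest-MI deciles). Per decile, the medians of
#' `mi_norm`, `synergy`, `redundancy`, `mvte`, and `mvte - redundancy` are
#' reported. Flagged triads are dropped first.
#'
#' @param triads Triad data.frame (see [evaluateTriads()]) with at least
#'   columns `mi_norm`, `synergy`, `redundancy`, `mvte`; an optional
#'   `flagged` column marks rows to exclude.
#' @return data.frame with 10 rows (`decile`, `mi_norm`, `synergy`,
#'   `redundancy`, `mvte`, `trans_minus_red`, `n_triads`) and attribute
#'   `usable` (`FALSE` when fewer than 10 usable triads were available, in
#'   which case all medians are `NA`).
#' @export
decileSummarize <- function(triads) {
  if (!all(.decileTerms %in% names(triads)))
    stop("triads must have columns: ", paste(.decileTerms, collapse = ", "))
  if ("flagged" %in% names(triads)) triads <- triads[!triads$flagged, , drop = FALSE]
  triads <- triads[!is.na(triads$mi_norm), , drop = FALSE]
  n <- nrow(triads)
  out <- data.frame(decile = 1:10, mi_norm = NA_real_, synergy = NA_real_,
                    redundancy = NA_real_, mvte = NA_real_,
                    trans_minus_red = NA_real_, n_triads = 0L)
  if (n < 10L) {
    attr(out, "usable") <- FALSE
    return(out)
  }
  ord <- order(triads$mi_norm)
  triads <- triads[ord, , drop = FALSE]
  base <- n %/% 10L
  extra <- n %% 10L
  counts <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  idx <- rep(1:10, counts)
  med <- function(v) as.numeric(tapply(v, idx, stats::median))
  out$mi_norm <- med(triads$mi_norm)
  out$synergy <- med(triads$synergy)
  out$redundancy <- med(triads$redundancy)
  out$mvte <- med(triads$mvte)
  out$trans_minus_red <- med(triads$mvte - triads$redundancy)
  out$n_triads <- counts
  attr(out, "usable") <- TRUE
  out
}

#' Spearman correlation between two terms across deciles
#'
#' @param summary Decile summary from [decileSummarize()].
#' @param xTerm,yTerm Column names (e.g. `"mi_norm"`, `"synergy"`).
#' @return Spearman rank correlation over the 10 decile medians
#'   (average ranks on ties), `NA` if any decile median is missing.
#' @export
termCorrelation <- function(summary, xTerm = "mi_norm", yTerm = "synergy") {
  x <- summary[[xTerm]]
  y <- summary[[yTerm]]
  if (is.null(x) || is.null(y)) stop("unknown term column")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Least-squares fit of one term against another across deciles
#'
#' Ordinary least squares on the 10 decile medians, in log10-log10 space by
#' default (slope in Delta log10(y) / Delta log10(x) units). Nonpositive
#' medians cannot be log-scaled; they are excluded and counted rather than
#' floored.
#'
#' @param summary Decile summary from [decileSummarize()].
#' @param xTerm,yTerm Column names.
#' @param logScale Fit in log10 space (default `TRUE`).
#' @return List with `slope`, `intercept`, `n_used`, `n_excluded`;
#'   slope/intercept are `NA` with fewer than 3 usable points.
#' @export
loglogFit <- function(summary, xTerm = "mi_norm", yTerm = "synergy",
                      logScale = TRUE) {
  x <- summary[[xTerm]]
  y <- summary[[yTerm]]
  if (is.null(x) || is.null(y)) stop("unknown term column")
  keep <- !is.na(x) & !is.na(y)
  if (logScale) keep <- keep & x > 0 & y > 0
  nExcluded <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (logScale) { x <- log10(x); y <- log10(y) }
  if (length(x) < 3L)
    return(list(slope = NA_real_, intercept = NA_real_,
                n_used = length(x), n_excluded = nExcluded))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n_used = length(x), n_excluded = nExcluded)
}

#' Percentile bootstrap confidence interval for the median
#'
#' @param values Numeric vector (at least one value).
#' @param nBoot Number of bootstrap resamples (default 10000).
#' @param seed Optional integer seed (deterministic CI given seed).
#' @param conf Confidence level (default 0.95).
#' @return List with `median`, `lo`, `hi`.
#' @export
bootstrapMedianCI <- function(values, nBoot = 10000, seed = NULL, conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("values must contain at least one non-missing value")
  run <- function() {
    boots <- vapply(seq_len(nBoot), function(i)
      stats::median(sample(values, length(values), replace = TRUE)), numeric(1))
    q <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                         names = FALSE, type = 7)
    list(median = stats::median(values), lo = q[1L], hi = q[2L])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Wilcoxon signed-rank test (normal approximation, Z reported)
#'
#' Two-sided one-sample signed-rank test of symmetry about `nullCenter`,
#' with average ranks on ties, zero differences dropped, and a tie
#' correction in the variance. The signed Z statistic is reported (positive
#' when values exceed the center).
#'
#' @param values Numeric vector.
#' @param nullCenter Hypothesized center (default 0).
#' @return List with `Z`, `p`, `n` (nonzero differences). `Z` and `p` are
#'   `NA` (flagged) when all differences are zero.
#' @export
signedRankTest <- function(values, nullCenter = 0) {
  d <- values[!is.na(values)] - nullCenter
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(Z = NA_real_, p = NA_real_, n = 0L))
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  z <- (wPlus - mu) / sqrt(sigma2)
  list(Z = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Wilcoxon rank-sum test (normal approximation, Z reported)
#'
#' Two-sided two-sample Mann-Whitney test with average ranks and tie
#' correction. Z is positive when `groupA` tends to exceed `groupB`.
#'
#' @param groupA,groupB Numeric vectors.
#' @return List with `Z`, `p`, `nA`, `nB`.
#' @export
rankSumTest <- function(groupA, groupB) {
  groupA <- groupA[!is.na(groupA)]
  groupB <- groupB[!is.na(groupB)]
  nA <- length(groupA); nB <- length(groupB)
  if (nA == 0L || nB == 0L) stop("both groups must be nonempty")
  r <- rank(c(groupA, groupB))
  wA <- sum(r[seq_len(nA)])
  mu <- nA * (nB + nA + 1) / 2
  nTot <- nA + nB
  tie <- table(r)
  sigma2 <- nA * nB / 12 * ((nTot + 1) - sum(tie^3 - tie) / (nTot * (nTot - 1)))
  if (sigma2 <= 0) return(list(Z = 0, p = 1, nA = nA, nB = nB))
  z <- (wA - mu) / sqrt(sigma2)
  list(Z = z, p = 2 * stats::pnorm(-abs(z)), nA = nA, nB = nB)
}

#' Bonferroni-Holm correction
#'
#' Step-down Holm adjustment of a vector of p-values (monotone, capped
#' at 1).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holmCorrect <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Sender-correlation level at which synergy peaks
#'
#' For each network's decile summary, the decile-median `mi_norm` at which
#' the decile-median synergy is maximal; across networks, the median of
#' that value with a bootstrap CI. Networks whose synergy peaks at the
#' first or last decile are counted as boundary cases (a monotone synergy
#' curve has no interior saturation point).
#'
#' @param summaries List of decile summaries ([decileSummarize()]).
#' @param nBoot,seed Passed to [bootstrapMedianCI()].
#' @return List with `mi_at_peak` (per network), `median`, `lo`, `hi`,
#'   `n_boundary`.
#' @export
saturationPoint <- function(summaries, nBoot = 10000, seed = NULL) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  miAtPeak <- rep(NA_real_, length(summaries))
  boundary <- logical(length(summaries))
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]
    if (anyNA(s$synergy)) next
    k <- which.max(s$synergy)
    miAtPeak[i] <- s$mi_norm[k]
    boundary[i] <- k %in% c(1L, nrow(s))
  }
  ok <- !is.na(miAtPeak)
  if (!any(ok)) stop("no usable decile summaries")
  ci <- bootstrapMedianCI(miAtPeak[ok], nBoot = nBoot, seed = seed)
  list(mi_at_peak = miAtPeak, median = ci$median, lo = ci$lo, hi = ci$hi,
       n_boundary = sum(boundary[ok]))
}

#' Per-network regression and correlation statistics
#'
#' For one network's decile summary: Spearman correlation, log-log slope
#' and intercept, and linear-space slope of each information term against
#' sender mutual information.
#'
#' @param summary Decile summary from [decileSummarize()].
#' @param yTerms Terms to relate to `mi_norm`.
#' @return data.frame with one row per term: `term`, `spearman_r`,
#'   `slope_log`, `intercept_log`, `slope_linear`.
#' @export
networkStats <- function(summary,
                         yTerms = c("synergy", "redundancy", "mvte",
                                    "trans_minus_red")) {
  rows <- lapply(yTerms, function(tm) {
    fl <- loglogFit(summary, "mi_norm", tm, logScale = TRUE)
    ll <- loglogFit(summary, "mi_norm", tm, logScale = FALSE)
    data.frame(term = tm,
               spearman_r = termCorrelation(summary, "mi_norm", tm),
               slope_log = fl$slope, intercept_log = fl$intercept,
               slope_linear = ll$slope)
  })
  do.call(rbind, rows)
}

#' Compare a statistic between synaptic and extrasynaptic timescale groups
#'
#' Rank-sum comparison of a per-network statistic between networks analyzed
#' at synaptic timescales (ids 1-3, centers 3/5/11 ms) and extrasynaptic
#' timescales (ids 7-9, centers 225/485/1044 ms).
#'
#' @param values Numeric per-network statistic.
#' @param timescaleIds Integer timescale id per network.
#' @param nBoot,seed Passed to [bootstrapMedianCI()] for group medians.
#' @return List with `Z`, `p`, group sizes and bootstrap group medians.
#' @export
compareTimescaleGroups <- function(values, timescaleIds, nBoot = 10000,
                                   seed = NULL) {
  syn <- values[timescaleIds %in% 1:3]
  ext <- values[timescaleIds %in% 7:9]
  if (!length(syn) || !length(ext))
    stop("need networks in both the synaptic (1-3) and extrasynaptic (7-9) groups")
  rs <- rankSumTest(syn, ext)
  list(Z = rs$Z, p = rs$p, n_synaptic = rs$nA, n_extrasynaptic = rs$nB,
       synaptic = bootstrapMedianCI(syn, nBoot = nBoot, seed = seed),
       extrasynaptic = bootstrapMedianCI(ext, nBoot = nBoot, seed = seed))
}
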