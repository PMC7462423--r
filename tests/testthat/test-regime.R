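mkTriads <- function(mi, syn = mi, red = 0.3 * syn, mvte = NULL) {
  if (is.null(mvte)) mvte <- syn + red + 0.2 * syn
  data.frame(mi_norm = mi, synergy = syn, redundancy = red, mvte = mvte)
}

test_that("decile medians partition triads into near-equal sorted bins", {
  tab <- decileSummarize(mkTriads(mi = 1:20))
  expect_equal(tab$mi_norm, seq(1.5, 19.5, by = 2))
  expect_equal(tab$n_triads, rep(2L, 10))
  # identical triads -> identical decile medians
  same <- decileSummarize(mkTriads(mi = rep(2, 30)))
  expect_equal(same$mi_norm, rep(2, 10))
  expect_equal(length(unique(same$synergy)), 1L)
  # synergy monotone in mi -> decile synergy medians strictly increasing
  mono <- decileSummarize(mkTriads(mi = 1:50, syn = (1:50)^2))
  expect_true(all(diff(mono$synergy) > 0))
  expect_true(all(diff(mono$mi_norm) > 0))
})

test_that("decile partition conserves triads and spreads the remainder low", {
  tab <- decileSummarize(mkTriads(mi = seq_len(47)))
  expect_equal(sum(tab$n_triads), 47L)
  expect_equal(tab$n_triads, c(rep(5L, 7), rep(4L, 3)))
  expect_lte(max(tab$n_triads) - min(tab$n_triads), 1L)
  few <- decileSummarize(mkTriads(mi = 1:5))
  expect_false(attr(few, "usable"))
  expect_true(all(is.na(few$mi_norm)))
})

test_that("term correlation matches a first-principles rank oracle", {
  s <- decileSummarize(mkTriads(mi = 1:30, syn = (1:30)^1.3))
  expect_equal(termCorrelation(s, "mi_norm", "synergy"), 1)
  sDec <- decileSummarize(mkTriads(mi = 1:30, syn = 31 - (1:30)))
  expect_equal(termCorrelation(sDec, "mi_norm", "synergy"), -1)
  withr::with_seed(14, {
    noisy <- decileSummarize(mkTriads(mi = 1:100,
                                      syn = (1:100)^0.5 * exp(rnorm(100, 0, 1))))
    expect_equal(termCorrelation(noisy, "mi_norm", "synergy"),
                 oracleSpearman(noisy$mi_norm, noisy$synergy))
  })
})

test_that("log-log fits recover planted power laws and linear fits linear laws", {
  mi <- exp(seq(log(0.001), log(0.5), length.out = 40))
  s <- decileSummarize(mkTriads(mi = mi, syn = 3 * mi^0.5))
  fit <- loglogFit(s, "mi_norm", "synergy")
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$n_used, 10L)
  flat <- decileSummarize(mkTriads(mi = mi, syn = rep(2, 40)))
  expect_equal(loglogFit(flat, "mi_norm", "synergy")$slope, 0, tolerance = 1e-10)
  lin <- loglogFit(decileSummarize(mkTriads(mi = mi, syn = 2 * mi)),
                   "mi_norm", "synergy", logScale = FALSE)
  expect_equal(lin$slope, 2, tolerance = 1e-10)
  expect_equal(lin$intercept, 0, tolerance = 1e-10)
  # nonpositive medians are excluded and counted, not floored
  szero <- decileSummarize(mkTriads(mi = mi, syn = c(rep(0, 8), 3 * mi[-(1:8)]^0.5)))
  f0 <- loglogFit(szero, "mi_norm", "synergy")
  expect_gt(f0$n_excluded, 0L)
})

test_that("bootstrap median CIs are deterministic and collapse on constants", {
  cc <- bootstrapMedianCI(rep(3.5, 20), nBoot = 200, seed = 1)
  expect_equal(c(cc$lo, cc$hi), c(3.5, 3.5))
  expect_error(bootstrapMedianCI(numeric()), "at least one")
  withr::with_seed(17, {
    x <- rnorm(50)
    c1 <- bootstrapMedianCI(x, nBoot = 500, seed = 4)
    c2 <- bootstrapMedianCI(x, nBoot = 500, seed = 4)
    expect_identical(c1, c2)
    expect_lte(c1$lo, c1$median)
    expect_gte(c1$hi, c1$median)
  })
})

test_that("bootstrap CIs cover the true median at roughly the nominal rate", {
  hits <- withr::with_seed(23, {
    vapply(1:100, function(i) {
      ci <- bootstrapMedianCI(rnorm(100), nBoot = 300)
      ci$lo <= 0 && ci$hi >= 0
    }, logical(1))
  })
  expect_gte(mean(hits), 0.85)  # nominal 95%, small-sample slack
})

test_that("signed-rank Z matches the closed form in the untied one-sided case", {
  # 75 distinct values all above the center: W+ = n(n+1)/2, so
  # Z = [n(n+1)/4] / sqrt(n(n+1)(2n+1)/24)
  n <- 75
  zMax <- (n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  res <- signedRankTest(1:75, nullCenter = 0)
  expect_equal(res$Z, zMax, tolerance = 1e-12)
  expect_equal(res$Z, 7.5249, tolerance = 1e-4)
  # antisymmetry and the symmetric null
  expect_equal(signedRankTest(-(1:75))$Z, -zMax, tolerance = 1e-12)
  sym <- signedRankTest(c(-(1:20), 1:20))
  expect_lt(abs(sym$Z), 1e-10)
  expect_equal(sym$p, 1, tolerance = 1e-6)
  # zero differences are dropped; all-zero input is flagged
  expect_true(is.na(signedRankTest(rep(0, 10))$Z))
})

test_that("rank-sum Z matches the closed form for fully separated groups", {
  nA <- 75; nB <- 75
  wMax <- sum((nB + 1):(nB + nA))
  mu <- nA * (nA + nB + 1) / 2
  zSep <- (wMax - mu) / sqrt(nA * nB * (nA + nB + 1) / 12)
  res <- rankSumTest(101:175, 1:75)
  expect_equal(res$Z, zSep, tolerance = 1e-12)
  expect_equal(res$Z, 10.5714, tolerance = 1e-4)
  expect_equal(rankSumTest(1:75, 101:175)$Z, -zSep, tolerance = 1e-12)
  expect_equal(rankSumTest(1:50, 1:50)$Z, 0)
})

test_that("Holm correction matches its definition and is monotone", {
  expect_equal(holmCorrect(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holmCorrect(0.03), 0.03)
  withr::with_seed(2, {
    p <- runif(12)
    adj <- holmCorrect(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  })
  expect_error(holmCorrect(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the saturation point is the decile MI at peak synergy", {
  mi <- exp(seq(log(0.001), log(1), length.out = 50))
  peaked <- mkTriads(mi = mi, syn = exp(-(log10(mi) + 1.2)^2))
  s <- decileSummarize(peaked)
  sat <- saturationPoint(list(s), nBoot = 100, seed = 1)
  expect_equal(sat$median, s$mi_norm[which.max(s$synergy)])
  expect_equal(sat$n_boundary, 0L)
  # strictly increasing synergy peaks at the top decile -> boundary flagged
  mono <- decileSummarize(mkTriads(mi = mi, syn = mi^0.5))
  satMono <- saturationPoint(list(mono), nBoot = 100, seed = 1)
  expect_equal(satMono$median, mono$mi_norm[10])
  expect_equal(satMono$n_boundary, 1L)
})

test_that("network statistics bundle correlation and fits per term", {
  mi <- exp(seq(log(0.001), log(0.5), length.out = 60))
  tri <- mkTriads(mi = mi, syn = mi^0.46, red = 0.2 * mi^0.8)
  st <- networkStats(decileSummarize(tri))
  expect_equal(st$term, c("synergy", "redundancy", "mvte", "trans_minus_red"))
  expect_equal(st$spearman_r[st$term == "synergy"], 1)
  expect_equal(st$slope_log[st$term == "synergy"], 0.46, tolerance = 1e-8)
  expect_equal(st$slope_log[st$term == "redundancy"], 0.8, tolerance = 1e-8)
})

test_that("group comparison requires both timescale groups and reports Z", {
  vals <- c(rnorm(6, 10), rnorm(6, 0))
  ids <- c(rep(1L, 6), rep(8L, 6))
  cmp <- compareTimescaleGroups(vals, ids, nBoot = 100, seed = 1)
  expect_gt(cmp$Z, 2)
  expect_equal(cmp$n_synaptic, 6L)
  expect_error(compareTimescaleGroups(vals, rep(1L, 12)), "both")
})

test_that("the pipeline rejects invalid configurations before any compute", {
  expect_error(runPipeline(list(timescales = 2)), "recordings")
  expect_error(runPipeline(list(recordings = list(randomRecording()))),
               "timescales")
  expect_error(runPipeline(list(recordings = list("/nonexistent/file.tsv"),
                                timescales = 2)), "not found")
})
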