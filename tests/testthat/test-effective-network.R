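test_that("jitter surrogates preserve spike count and respect the window", {
  withr::with_seed(1, {
    train <- sort(runif(300, 0, 60))
    jit <- jitterSurrogate(train, halfWindowMs = 50, duration = 60, seed = 4)
    expect_equal(length(jit), length(train))
    expect_false(is.unsorted(jit))
    expect_true(all(jit >= 0 & jit <= 60))
    # displacement bounded by the half-window, sample mean near zero
    delta <- sort(jit) - sort(train)
    expect_lte(max(abs(delta)), 0.05 + 1e-12)
    expect_lt(abs(mean(delta)), 3 * 0.05 / sqrt(3 * 300))
    # tiny window: surrogate approaches the original train
    jit0 <- jitterSurrogate(train, halfWindowMs = 1e-6, duration = 60, seed = 5)
    expect_equal(jit0, train, tolerance = 1e-8)
  })
})

test_that("strong lagged coupling is detected and zero TE never is", {
  spec <- list(id = NA, bin_width_ms = 5, delays = 1:4)
  withr::with_seed(11, {
    src <- sort(runif(400, 0, 40))
    tgtTimes <- src + 0.008  # 8 ms lag -> delay 2 at 5 ms bins
    tgt <- states(binSpikes(SpikeRecording(list(`1` = tgtTimes), 40), 5))[1, ]
  })
  res <- connectionSignificance(src, tgt, duration = 40, spec = spec,
                                nJitter = 200, alpha = 0.01, seed = 2)
  expect_true(res$significant)
  expect_equal(res$peak_delay, 2L)
  # a source with no spikes has TE exactly 0: never significant
  res0 <- connectionSignificance(numeric(0), tgt, duration = 40, spec = spec,
                                 nJitter = 30, alpha = 0.05, seed = 3)
  expect_equal(res0$te, 0)
  expect_equal(res0$p_value, 1)
  expect_error(connectionSignificance(src, tgt, 40, spec, nJitter = 5,
                                      alpha = 0.001), "configuration error")
})

test_that("a driven chain is recovered without reverse edges", {
  # A drives B drives C with 4 ms lags; analyzed at the 3.5-ms timescale
  withr::with_seed(21, {
    a <- sort(runif(500, 0, 50))
    b <- sort(c(a + 0.004, runif(60, 0, 50)))
    c_ <- sort(c(b + 0.004, runif(60, 0, 50)))
    rec <- SpikeRecording(list(`1` = a, `2` = b[b < 50], `3` = c_[c_ < 50]),
                          duration = 50)
  })
  net <- buildEffectiveNetwork(rec, getTimescale(3), nJitter = 99,
                               alpha = 0.02, seed = 31)
  ed <- edges(net)
  key <- paste(ed$source, ed$target, sep = "->")
  expect_true(all(c("1->2", "2->3") %in% key))
  expect_false(any(c("2->1", "3->2", "3->1") %in% key))
  # determinism: identical edge set under the same seed
  net2 <- buildEffectiveNetwork(rec, getTimescale(3), nJitter = 99,
                                alpha = 0.02, seed = 31)
  expect_identical(edges(net), edges(net2))
})

test_that("triad enumeration counts C(indegree, 2) per receiver", {
  mkNet <- function(src, tgt) {
    ed <- data.frame(source = src, target = tgt, te = 0.1, te_norm = 0.1,
                     peak_delay = 1L, p_value = 1e-4)
    new("EffectiveNetwork", edges = ed, timescale = getTimescale(3),
        neuronIds = as.integer(union(src, tgt)), alpha = 0.001, nJitter = 10)
  }
  tri <- enumerateTriads(mkNet(c(1, 2, 3), c(3, 3, 4)))
  expect_equal(nrow(tri), 1L)
  expect_equal(unlist(tri[1, ], use.names = FALSE), c(1L, 2L, 3L))
  # receiver with in-degree 4 -> 6 triads
  tri4 <- enumerateTriads(mkNet(1:4, rep(5, 4)))
  expect_equal(nrow(tri4), choose(4, 2))
  # empty network -> empty triad list
  empty <- new("EffectiveNetwork",
               edges = data.frame(source = integer(), target = integer(),
                                  te = numeric(), te_norm = numeric(),
                                  peak_delay = integer(), p_value = numeric()),
               timescale = getTimescale(3), neuronIds = 1:3, alpha = 0.001,
               nJitter = 10)
  expect_equal(nrow(enumerateTriads(empty)), 0L)
})

test_that("triad evaluation reproduces duplication algebra and the PID identity", {
  # senders are identical trains driving a copy receiver
  rec <- generateTriad(rateJ = 40, rateK = 40, commonDrive = 1,
                       gate = "copy_j", lagMs = 4, reliability = 1,
                       backgroundRate = 0, duration = 30, seed = 5,
                       genBinMs = 4)
  spec <- list(id = NA, bin_width_ms = 4, delays = 1:4)
  net <- buildEffectiveNetwork(rec, spec, nJitter = 99, alpha = 0.02, seed = 6)
  tri <- enumerateTriads(net)
  tri <- tri[tri$receiver == 3 & tri$sender_j == 1 & tri$sender_k == 2, ]
  expect_equal(nrow(tri), 1L)  # fully reliable copy drive is always recovered
  tab <- evaluateTriads(rec, net, triads = tri)
  expect_equal(tab$mi_norm, 1)
  expect_lt(tab$synergy, 1e-10)
  expect_equal(tab$unique_j + tab$unique_k + tab$redundancy + tab$synergy,
               tab$mvte, tolerance = 1e-10)
  expect_equal(tab$redundancy, tab$te_j, tolerance = 1e-10)
})

test_that("an XOR triad is dominated by synergy with uncorrelated senders", {
  rec <- generateTriad(rateJ = 400, rateK = 400, commonDrive = 0,
                       gate = "xor", lagMs = 2, reliability = 1,
                       backgroundRate = 0, duration = 40, seed = 8,
                       genBinMs = 1)
  raster <- states(binSpikes(rec, 1))
  j <- raster[1, ]; k <- raster[2, ]; i <- raster[3, ]
  expect_lt(mutualInformationNorm(j, k), 0.01)
  pid <- normalizePID(pidDecompose(j, k, i, 2, 2), receiver = i)
  # symmetric XOR: redundancy equals the (small) bivariate TE, so it stays
  # below ~H(occupancy) * 0.1 while synergy carries almost all of the mvTE
  expect_lt(pid@redundancy, 0.1)
  expect_gt(pid@synergy, 0.85 * pid@mvte)
  expect_lt(pid@teJ, 0.1)
})

test_that("network export round-trips the edge list", {
  ed <- data.frame(source = c(1L, 2L), target = c(3L, 3L), te = c(0.2, 0.1),
                   te_norm = c(0.4, 0.2), peak_delay = c(1L, 2L),
                   p_value = c(1e-4, 2e-4))
  net <- new("EffectiveNetwork", edges = ed, timescale = getTimescale(2),
             neuronIds = 1:3, alpha = 0.001, nJitter = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  exportNetwork(net, f)
  back <- utils::read.delim(f)
  expect_equal(back$source, ed$source)
  expect_equal(back$normalized_te, ed$te_norm)
  g <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, g, format = "graphml")
  expect_gt(file.size(g), 0)
})
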