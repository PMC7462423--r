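# Independent brute-force oracles: everything here is computed by explicit
# summation loops over joint-table cells, never via the package's
# vectorized implementations.

oracleEntropy <- function(p) {
  h <- 0
  for (v in as.numeric(p)) if (v > 0) h <- h - v * log2(v)
  h
}

# p: matrix p(x, y) -> MI / min marginal entropy
oracleMINorm <- function(p) {
  px <- rowSums(p); py <- colSums(p)
  hx <- oracleEntropy(px); hy <- oracleEntropy(py)
  if (hx == 0 || hy == 0) return(NA_real_)
  mi <- 0
  for (x in seq_len(nrow(p))) for (y in seq_len(ncol(p))) {
    if (p[x, y] > 0) mi <- mi + p[x, y] * log2(p[x, y] / (px[x] * py[y]))
  }
  mi / min(hx, hy)
}

# p: 3-d array (i_t, i_p, j)
oracleTE <- function(p) {
  d <- dim(p)
  te <- 0
  for (it in 1:d[1]) for (ip in 1:d[2]) for (j in 1:d[3]) {
    pv <- p[it, ip, j]
    if (pv > 0) {
      p_ipj <- sum(p[, ip, j])
      p_itip <- sum(p[it, ip, ])
      p_ip <- sum(p[, ip, ])
      te <- te + pv * log2((pv / p_ipj) / (p_itip / p_ip))
    }
  }
  te
}

# p: 4-d array (i_t, i_p, j, k)
oracleMVTE <- function(p) {
  d <- dim(p)
  te <- 0
  for (it in 1:d[1]) for (ip in 1:d[2]) for (j in 1:d[3]) for (k in 1:d[4]) {
    pv <- p[it, ip, j, k]
    if (pv > 0) {
      p_ipjk <- sum(p[, ip, j, k])
      p_itip <- sum(p[it, ip, , ])
      p_ip <- sum(p[, ip, , ])
      te <- te + pv * log2((pv / p_ipjk) / (p_itip / p_ip))
    }
  }
  te
}

# specific information of source s (3 = j, 4 = k) about i_t given i_p
oracleIspec <- function(p, it, ip, sourceDim) {
  d <- dim(p)
  p_itip <- sum(p[it, ip, , ])
  if (p_itip == 0) return(0)
  p_ip <- sum(p[, ip, , ])
  val <- 0
  for (s in seq_len(d[sourceDim])) {
    p_itips <- if (sourceDim == 3) sum(p[it, ip, s, ]) else sum(p[it, ip, , s])
    if (p_itips == 0) next
    p_ips <- if (sourceDim == 3) sum(p[, ip, s, ]) else sum(p[, ip, , s])
    ps_given <- p_itips / p_itip
    val <- val + ps_given * (log2(p_itips / p_ips) - log2(p_itip / p_ip))
  }
  val
}

# full I_min PID by explicit summation
oraclePID <- function(p) {
  d <- dim(p)
  pj3 <- array(0, d[c(1, 2, 3)])
  pk3 <- array(0, d[c(1, 2, 4)])
  for (it in 1:d[1]) for (ip in 1:d[2]) {
    for (j in 1:d[3]) pj3[it, ip, j] <- sum(p[it, ip, j, ])
    for (k in 1:d[4]) pk3[it, ip, k] <- sum(p[it, ip, , k])
  }
  teJ <- oracleTE(pj3)
  teK <- oracleTE(pk3)
  mvte <- oracleMVTE(p)
  red <- 0
  for (it in 1:d[1]) for (ip in 1:d[2]) {
    p_itip <- sum(p[it, ip, , ])
    if (p_itip > 0)
      red <- red + p_itip * min(oracleIspec(p, it, ip, 3),
                                oracleIspec(p, it, ip, 4))
  }
  syn <- mvte - teJ - teK + red
  c(te_j = teJ, te_k = teK, mvte = mvte, redundancy = red, synergy = syn,
    unique_j = teJ - red, unique_k = teK - red)
}

# average-rank Spearman by first principles (order-based average ranks,
# then the Pearson product-moment formula on the ranks)
oracleSpearman <- function(x, y) {
  avrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- avrank(x); ry <- avrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# random joint probability array via normalized gamma draws
randomTable <- function(dims, seed) {
  withr::with_seed(seed, {
    g <- stats::rgamma(prod(dims), shape = 1)
    array(g / sum(g), dim = dims)
  })
}

# exact structured tables over (i_t, i_p, j, k), binary everywhere
xorTable <- function() {
  p <- array(0, c(2, 2, 2, 2))
  for (ip in 0:1) for (j in 0:1) for (k in 0:1)
    p[xor(j == 1, k == 1) + 1, ip + 1, j + 1, k + 1] <- 1 / 8
  p
}
copyTable <- function() {
  p <- array(0, c(2, 2, 2, 2))
  for (ip in 0:1) for (j in 0:1) for (k in 0:1)
    p[j + 1, ip + 1, j + 1, k + 1] <- 1 / 8
  p
}
dupSenderTable <- function() {
  p <- array(0, c(2, 2, 2, 2))
  for (ip in 0:1) for (j in 0:1) p[j + 1, ip + 1, j + 1, j + 1] <- 1 / 4
  p
}
independentTable <- function() {
  array(1 / 16, c(2, 2, 2, 2))
}

# empirical 4-d table from aligned sequences, counted by explicit loop
oracleEmpirical4 <- function(j, k, i, dJ, dK) {
  n <- length(i)
  dmax <- max(dJ, dK)
  counts <- array(0, c(max(i) + 1, max(i) + 1, max(j) + 1, max(k) + 1))
  for (t in (dmax + 1):n) {
    counts[i[t] + 1, i[t - 1] + 1, j[t - dJ] + 1, k[t - dK] + 1] <-
      counts[i[t] + 1, i[t - 1] + 1, j[t - dJ] + 1, k[t - dK] + 1] + 1
  }
  counts / sum(counts)
}

# small random recording fixture
randomRecording <- function(nNeurons = 4, rate = 5, duration = 10, seed = 1) {
  withr::with_seed(seed, {
    spikes <- lapply(seq_len(nNeurons), function(i)
      sort(stats::runif(stats::rpois(1, rate * duration), 0, duration)))
    names(spikes) <- as.character(seq_len(nNeurons))
    SpikeRecording(spikes, duration = duration, label = "fixture")
  })
}
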