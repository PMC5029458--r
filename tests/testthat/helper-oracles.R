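# Brute-force enumeration oracles, deliberately different algorithms from
# the package's convolution/fisher.test routines.

# two-sided signed-rank p by enumerating all 2^n sign vectors
oracleSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L])
  }, numeric(1))
  pLe <- mean(ws <= obs + 1e-9)
  pGe <- mean(ws >= obs - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# two-sided rank-sum p by enumerating all C(n+m, n) group assignments
oracleRankSumP <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n)])
  ws <- apply(utils::combn(n + m, n), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= obs + 1e-9), mean(ws >= obs - 1e-9)))
}

# two-tailed Fisher p by full hypergeometric enumeration
oracleFisherP <- function(k, a, b, N) {
  ks <- max(0, a + b - N):min(a, b)
  pr <- choose(b, ks) * choose(N - b, a - ks) / choose(N, a)
  pObs <- pr[ks == k]
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# gene-universe helper for hotspotOverlap against the oracle
overlapSets <- function(k, a, b, N) {
  g <- sprintf("g%03d", seq_len(N))
  list(ma = g[seq_len(a)],
       hotspot = g[c(seq_len(k), a + seq_len(b - k))],
       background = g)
}
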