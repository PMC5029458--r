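## Exact Wilcoxon null distributions by convolution.
##
## stats::wilcox.test declines to compute exact p-values in the presence of
## tied ranks, but tied (average) ranks arise routinely in paired beta-value
## differences; the convolution below conditions on the observed rank vector
## (integerized as 2*rank) and so handles ties exactly. Two-sided p is
## 2*min(lower, upper) tail, capped at 1 — identical to the wilcox.test
## convention in the tie-free case.

# distribution of sum over random subsets (each rank included w.p. 1/2)
signedRankNull <- function(ranks2) {
  tot <- sum(ranks2)
  f <- numeric(tot + 1); f[1] <- 1
  for (k in ranks2) {
    g <- f
    idx <- (k + 1):(tot + 1)
    g[idx] <- g[idx] + f[idx - k]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Exact Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (the Wilcoxon convention); tied absolute
#' differences receive average ranks and the exact null distribution is
#' computed by convolution conditional on those ranks. With no nonzero
#' differences the p-value is 1.
#'
#' @param d numeric vector of paired differences
#' @return list with \code{statistic} (V, the positive-rank sum),
#'   \code{p_value} (two-sided) and \code{n} (nonzero pairs)
#' @examples
#' exactSignedRank(rep(0.1, 6))$p_value  # 2/2^6 = 0.03125
#' @export
exactSignedRank <- function(d) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n = 0L))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  f <- signedRankNull(as.integer(round(2 * r)))
  v2 <- as.integer(round(2 * v))
  pLe <- sum(f[seq_len(v2 + 1)])
  pGe <- sum(f[(v2 + 1):length(f)])
  list(statistic = v, p_value = min(1, 2 * min(pLe, pGe)), n = n)
}

# distribution of the rank sum of n items drawn from pooled ranks2
rankSumNull <- function(ranks2, n) {
  tot <- sum(ranks2)
  # f[k+1, s+1] = number of k-subsets with rank2-sum s
  f <- matrix(0, n + 1, tot + 1)
  f[1, 1] <- 1
  for (v in ranks2) {
    for (k in min(n, nrow(f) - 1):1) {
      idx <- (v + 1):(tot + 1)
      f[k + 1, idx] <- f[k + 1, idx] + f[k, idx - v]
    }
  }
  f[n + 1, ] / choose(length(ranks2), n)
}

#' Exact Wilcoxon rank-sum test
#'
#' Exact two-sided p-value by convolution over all assignments of the
#' pooled (possibly tied, average) ranks; the statistic is the Mann-Whitney
#' W of \code{x}, as in \code{stats::wilcox.test}.
#'
#' @param x,y the two groups
#' @return list with \code{statistic}, \code{p_value}, \code{n}
#' @examples
#' exactRankSum(1:3, 4:6)$p_value  # 0.1
#' @export
exactRankSum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  wx <- sum(r[seq_len(n)])
  f <- rankSumNull(as.integer(round(2 * r)), n)
  w2 <- as.integer(round(2 * wx))
  pLe <- sum(f[seq_len(w2 + 1)])
  pGe <- sum(f[(w2 + 1):length(f)])
  list(statistic = wx - n * (n + 1) / 2,
       p_value = min(1, 2 * min(pLe, pGe)), n = c(n, m))
}
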