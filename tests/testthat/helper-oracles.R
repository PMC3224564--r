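# Independent oracles used across tests.

# Exhaustive circular maximal-t by direct evaluation of the statistic over
# the full (i, j) matrix -- a deliberately different code path from the
# package's per-k prefix-sum scan.
brute_force_scan <- function(r, min_width = 2L) {
  n <- length(r)
  S <- c(0, cumsum(r))
  s <- sd(r)
  ij <- expand.grid(i = 0:n, j = 0:n)
  k <- ij$j - ij$i
  ok <- k >= min_width & k <= n - min_width
  ij <- ij[ok, ]
  k <- k[ok]
  sij <- S[ij$j + 1] - S[ij$i + 1]
  tt <- (sij / k - (S[n + 1] - sij) / (n - k)) / (s * sqrt(1 / k + 1 / (n - k)))
  best <- which.max(abs(tt))
  list(t_max = tt[best], abs_t_max = abs(tt[best]),
       i = ij$i[best], j = ij$j[best], all_t = tt, all_i = ij$i, all_j = ij$j)
}

# sample skewness / kurtosis (population-moment estimators)
sample_sk_ku <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  c(sk = mean((x - m)^3) / m2^1.5, ku = mean((x - m)^4) / m2^2)
}

# Monte-Carlo standard errors of the skewness/kurtosis estimators, from
# block resampling of the sample itself (no distributional assumptions)
block_se_sk_ku <- function(x, blocks = 20L) {
  idx <- cut(seq_along(x), blocks, labels = FALSE)
  est <- t(vapply(split(x, idx), sample_sk_ku, numeric(2)))
  apply(est, 2, sd) / sqrt(blocks)
}
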