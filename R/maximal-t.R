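#' Circular t statistic for one arc
#'
#' Computes the two-sample t-like statistic comparing the arc of probes
#' `i+1..j` of a circularized series with its complementary arc,
#' \deqn{T_{ij} = \frac{S_{ij}/k - (S_N - S_{ij})/(N-k)}
#'                     {s\sqrt{1/k + 1/(N-k)}},}
#' where \eqn{S_{ij}} is the arc sum, \eqn{k = j - i} and \eqn{s} is the
#' sample standard deviation (n-1 denominator) of the whole series.
#'
#' Indices follow the half-open convention `(i, j]` with `0 <= i < j <= N`;
#' `i = 0` (or `j = N`) represents a single change-point at `j` (or `i`).
#' Swapping arc and complement negates the statistic.
#'
#' @param r numeric vector of log2 ratios.
#' @param i,j integer arc end-points, `0 <= i < j <= N`, with arc width
#'   `k = j - i` satisfying `1 <= k <= N - 1`.
#' @return The statistic, a single numeric value.
#' @examples
#' t_statistic(c(0, 0, 0, 1, 1, 1), 3, 6)  #  2.236068
#' t_statistic(c(0, 0, 0, 1, 1, 1), 0, 3)  # -2.236068
#' @export
t_statistic <- function(r, i, j) {
  r <- as.numeric(r)
  n <- length(r)
  stopifnot(length(i) == 1L, length(j) == 1L)
  if (!(i >= 0 && i < j && j <= n)) stop("need 0 <= i < j <= N")
  k <- j - i
  if (k < 1 || k > n - 1) stop("arc width k = j - i must satisfy 1 <= k <= N - 1")
  s <- stats::sd(r)
  if (!(s > 0)) stop("degenerate series: sample standard deviation is zero")
  sij <- sum(r[seq.int(i + 1L, j)])
  (sij / k - (sum(r) - sij) / (n - k)) / (s * sqrt(1 / k + 1 / (n - k)))
}

#' Exhaustive circular maximal-t scan
#'
#' Locates the candidate change-point pair `(i_c, j_c)` maximizing
#' `|T_ij|` (see [t_statistic()]) over all arcs whose width and complementary
#' width are both at least `min_width`.  The scan is exhaustive (O(N^2),
#' implemented in C), so it equals brute-force evaluation exactly; ties in
#' `|T|` are broken toward the lexicographically smallest `(i, j)` for
#' determinism.
#'
#' @param r numeric vector of log2 ratios, length `N >= 2 * min_width`.
#' @param min_width minimum number of probes on each arc (default 2, so both
#'   arcs contribute variance).
#' @return A list with elements `t_max` (signed statistic at the argmax),
#'   `abs_t_max`, and the arc end-points `i`, `j`.
#' @examples
#' max_t_scan(c(0, 0, 0, 1, 1, 1))
#' @export
max_t_scan <- function(r, min_width = 2L) {
  r <- as.numeric(r)
  if (anyNA(r) || any(!is.finite(r))) stop("series contains non-finite values")
  n <- length(r)
  min_width <- as.integer(min_width)
  if (n < 2L * min_width)
    stop(sprintf("series too short: N = %d < 2 * min_width = %d", n, 2L * min_width))
  .scan_maxt_cpp(r, min_width)
}

# |T_max| for every column of a matrix of null series
tmax_batch <- function(x, min_width = 2L) {
  .tmax_batch_cpp(x, as.integer(min_width))
}
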