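#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Circular maximal-t scan.
//
// For a series r[0..N-1], index pairs (i, j) with 0 <= i < j <= N denote the
// arc of probes i+1..j (half-open (i, j]); the complementary arc is the rest
// of the circularized series.  T_ij compares the arc mean with the
// complement mean, standardized by the series standard deviation:
//
//   T_ij = (S_ij/k - (S_N - S_ij)/(N - k)) / (s * sqrt(1/k + 1/(N - k)))
//
// with S_ij the arc sum and k = j - i.  The scan is exhaustive; the per-k
// constants are hoisted so the inner loop is a prefix-sum difference, one
// fused multiply-add and a compare.

namespace {

struct ScanWork {
  std::vector<double> S;   // prefix sums, length N+1
  std::vector<double> A;   // 1/k + 1/(N-k)
  std::vector<double> B;   // S_N / (N-k)
  std::vector<double> D;   // s * sqrt(1/k + 1/(N-k))
};

// sample sd with n-1 denominator; returns 0 for constant series
double sample_sd(const double* r, int N) {
  double mean = 0.0;
  for (int i = 0; i < N; ++i) mean += r[i];
  mean /= N;
  double ss = 0.0;
  for (int i = 0; i < N; ++i) {
    double d = r[i] - mean;
    ss += d * d;
  }
  return std::sqrt(ss / (N - 1));
}

// Fill per-k tables; returns false when the series is (numerically) constant.
bool prepare(const double* r, int N, int min_width, ScanWork& w) {
  w.S.resize(N + 1);
  w.S[0] = 0.0;
  for (int i = 0; i < N; ++i) w.S[i + 1] = w.S[i] + r[i];
  double s = sample_sd(r, N);
  if (!(s > 0.0)) return false;
  w.A.assign(N + 1, 0.0);
  w.B.assign(N + 1, 0.0);
  w.D.assign(N + 1, 0.0);
  for (int k = min_width; k <= N - min_width; ++k) {
    double ck = 1.0 / k + 1.0 / (N - k);
    w.A[k] = ck;
    w.B[k] = w.S[N] / (double)(N - k);
    w.D[k] = s * std::sqrt(ck);
  }
  return true;
}

// Exhaustive scan keeping the argmax; ties in |T| broken toward the
// lexicographically smallest (i, j), which the (i outer, j inner) loop order
// yields with a strict '>' comparison.
void scan_argmax(const ScanWork& w, int N, int min_width,
                 double& t_best, double& abs_best, int& bi, int& bj) {
  abs_best = -1.0;
  t_best = 0.0;
  bi = -1;
  bj = -1;
  const double* S = w.S.data();
  const double* A = w.A.data();
  const double* B = w.B.data();
  const double* D = w.D.data();
  int kmax = N - min_width;
  for (int i = 0; i <= N - min_width; ++i) {
    int jhi = i + kmax;
    if (jhi > N) jhi = N;
    double Si = S[i];
    for (int j = i + min_width; j <= jhi; ++j) {
      int k = j - i;
      double t = ((S[j] - Si) * A[k] - B[k]) / D[k];
      double a = std::fabs(t);
      if (a > abs_best) {
        abs_best = a;
        t_best = t;
        bi = i;
        bj = j;
      }
    }
  }
}

// Max-only scan (no index bookkeeping) for permutations / null replicates.
double scan_max_only(const ScanWork& w, int N, int min_width) {
  double best = -1.0;
  const double* S = w.S.data();
  const double* A = w.A.data();
  const double* B = w.B.data();
  const double* D = w.D.data();
  int kmax = N - min_width;
  for (int i = 0; i <= N - min_width; ++i) {
    int jhi = i + kmax;
    if (jhi > N) jhi = N;
    double Si = S[i];
    for (int j = i + min_width; j <= jhi; ++j) {
      int k = j - i;
      double t = ((S[j] - Si) * A[k] - B[k]) / D[k];
      double a = std::fabs(t);
      if (a > best) best = a;
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".scan_maxt_cpp")]]
List scan_maxt_cpp(NumericVector r, int min_width) {
  int N = r.size();
  if (min_width < 1) stop("min_width must be >= 1");
  if (N < 2 * min_width) stop("series too short for the requested min_width");
  ScanWork w;
  if (!prepare(REAL(r), N, min_width, w))
    stop("degenerate series: sample standard deviation is zero");
  double t_best, abs_best;
  int bi, bj;
  scan_argmax(w, N, min_width, t_best, abs_best, bi, bj);
  return List::create(_["t_max"] = t_best, _["abs_t_max"] = abs_best,
                      _["i"] = bi, _["j"] = bj);
}

// |T_max| for each column of a matrix of series (null replicate batches).
// [[Rcpp::export(name = ".tmax_batch_cpp")]]
NumericVector tmax_batch_cpp(NumericMatrix x, int min_width) {
  int N = x.nrow(), R = x.ncol();
  if (N < 2 * min_width) stop("series too short for the requested min_width");
  NumericVector out(R);
  ScanWork w;
  for (int c = 0; c < R; ++c) {
    if (!prepare(&x(0, c), N, min_width, w))
      stop("degenerate series in column %d: zero standard deviation", c + 1);
    out[c] = scan_max_only(w, N, min_width);
  }
  return out;
}

// Permutation null for |T_max| with optional early stopping.  Uses R's RNG
// (seed controlled by set.seed in R).  Early stop fires as soon as the
// exceedance count alone guarantees the final add-one p-value exceeds alpha,
// so it can never change a decision at level alpha.
// [[Rcpp::export(name = ".perm_tmax_cpp")]]
List perm_tmax_cpp(NumericVector r, double t_obs_abs, int n_perm,
                   int min_width, double alpha, bool early_stop) {
  int N = r.size();
  if (N < 2 * min_width) stop("series too short for the requested min_width");
  std::vector<double> buf(REAL(r), REAL(r) + N);
  ScanWork w;
  // exceedances strictly needed before p > alpha is certain:
  // (1 + e) / (1 + n_perm) > alpha  <=>  e > alpha * (1 + n_perm) - 1
  double stop_at = alpha * (1.0 + n_perm) - 1.0;
  int exceed = 0, done = 0;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int k = N - 1; k > 0; --k) {
      int j = (int)(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(buf[k], buf[j]);
    }
    if (!prepare(buf.data(), N, min_width, w))
      stop("degenerate series: zero standard deviation");
    double m = scan_max_only(w, N, min_width);
    ++done;
    if (m >= t_obs_abs) ++exceed;
    if (early_stop && exceed > stop_at) break;
  }
  return List::create(_["exceed"] = exceed, _["n_done"] = done,
                      _["p_value"] = (1.0 + exceed) / (1.0 + done));
}
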