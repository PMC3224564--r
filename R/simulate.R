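#' Validation simulation, model 1: multi-segment chromosome
#'
#' 150 probes with four change-points at 50, 70, 80 and 100; segment means
#' `(0, cv, -cv, cv, 0)` and i.i.d. normal noise `N(m_i, v^2)`.  The
#' amplitude factor `c` controls the signal-to-noise ratio (the cases
#' `c = 2, 3, 4` are the reference settings).
#'
#' @param c_amp amplitude factor `c`.
#' @param v noise standard deviation (default 0.2, a typical aCGH noise
#'   level; the statistic is scale-invariant so only `c` matters for
#'   detection).
#' @param seed optional seed (`set.seed` is called when given).
#' @return A list with `series` (numeric, length 150) and `truth`
#'   (boundaries `c(50, 70, 80, 100)`, segment means, `n`, `c`, `v`).
#' @export
sim_model1 <- function(c_amp = 2, v = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!(v >= 0)) stop("v must be nonnegative")
  n <- 150L
  boundaries <- c(50L, 70L, 80L, 100L)
  means <- c(0, c_amp * v, -c_amp * v, c_amp * v, 0)
  seg_of <- findInterval(seq_len(n) - 1L, boundaries) + 1L
  mu <- means[seg_of]
  series <- mu + if (v > 0) stats::rnorm(n, 0, v) else 0
  list(series = series,
       truth = list(boundaries = boundaries, means = means, n = n,
                    c = c_amp, v = v))
}

#' Validation simulation, model 2: single aberration in a long chromosome
#'
#' 1,500 probes with one embedded aberration: mean `c*v` on the window of
#' `k` probes starting after position `l` (probes `l+1 .. l+k`), 0
#' elsewhere.  Noise is drawn from the Pearson system with skewness
#' `noise_sk` and kurtosis `noise_ku`, scaled to standard deviation `v`
#' (normal noise for `(0, 3)`).  `l = 0` places the aberration at the
#' chromosome edge (the ROC design, `k = 15`); `l = (N - k)/2` puts two
#' change-points in the center.  `c_amp = 0` yields a pure null series for
#' specificity runs.
#'
#' @param c_amp amplitude factor `c`.
#' @param v noise standard deviation.
#' @param k aberration width in probes.
#' @param l aberration location (`0 <= l <= N - k`).
#' @param noise_sk,noise_ku noise skewness and kurtosis.
#' @param seed optional seed.
#' @return A list with `series` (length 1,500) and `truth` (the cut points
#'   bounding the aberration that lie inside the chromosome, the window,
#'   and the generating parameters).
#' @export
sim_model2 <- function(c_amp = 2, v = 0.2, k = 15L, l = 0L, noise_sk = 0,
                       noise_ku = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 1500L
  k <- as.integer(k); l <- as.integer(l)
  if (l < 0L || l + k > n) stop("need 0 <= l <= N - k")
  mu <- rep(0, n)
  if (c_amp != 0 && k > 0) mu[(l + 1L):(l + k)] <- c_amp * v
  noise <- if (v > 0) rpearson(n, noise_sk, noise_ku, mean = 0, sd = v) else 0
  cuts <- integer(0)
  if (c_amp != 0 && k > 0) {
    if (l > 0L) cuts <- c(cuts, l)
    if (l + k < n) cuts <- c(cuts, l + k)
  }
  list(series = mu + noise,
       truth = list(cuts = cuts, window = if (k > 0) c(l + 1L, l + k) else NULL,
                    n = n, c = c_amp, v = v, k = k, l = l,
                    noise_sk = noise_sk, noise_ku = noise_ku))
}

#' ROC study: GEV lookup vs permutation significance
#'
#' Reproduces the power-validation design: an aberration of `k = 15` probes
#' at the chromosome edge (`l = 0`) of 1,500-probe series, detected by the
#' chromosome-level maximal-t test.  For each replicate an
#' aberration-bearing and a null series are generated; each is scanned once
#' and its maximal-t p-value is evaluated by each requested method on
#' identical data (the table-lookup path against `model`, and/or the
#' permutation path with `n_perm` permutations).  A replicate counts as
#' detectable only if the scanned boundaries match the true cut points
#' within `match_tol` probes; sensitivity at level alpha is the fraction of
#' aberration replicates with matching boundaries and p < alpha,
#' specificity the fraction of null replicates with p >= alpha.  The area
#' under the ROC curve is computed by the rank (Mann-Whitney) construction
#' over the paired p-value samples, equivalent to sweeping alpha over
#' [0, 1].
#'
#' @param model an `ecbs_model` (required for the `"gev"` method).
#' @param c_amp amplitude factor of the aberration.
#' @param v noise standard deviation.
#' @param noise_sk,noise_ku noise skewness and kurtosis.
#' @param n_rep replicates per arm (>= 100).
#' @param n_perm permutations per series for the permutation method.
#' @param methods subset of `c("gev", "permutation")`.
#' @param alpha_grid levels at which the sensitivity/specificity table is
#'   reported.
#' @param match_tol boundary matching tolerance in probes (default 2).
#' @param k,l aberration width and location.
#' @param cfg an [ecbs_config()] (supplies `min_width`).
#' @param seed seed for the whole study.
#' @return A list with `table` (method, alpha, sensitivity, specificity),
#'   `auc` (named by method), and the per-replicate p-values.
#' @export
roc_study <- function(model = NULL, c_amp = 1.5, v = 0.2, noise_sk = 0,
                      noise_ku = 3, n_rep = 500L, n_perm = 1000L,
                      methods = c("gev", "permutation"),
                      alpha_grid = c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05,
                                     0.1, 0.2, 0.5),
                      match_tol = 2L, k = 15L, l = 0L,
                      cfg = ecbs_config(), seed = 1L) {
  methods <- match.arg(methods, c("gev", "permutation"), several.ok = TRUE)
  if ("gev" %in% methods && is.null(model)) stop("the 'gev' method needs a model")
  n_rep <- as.integer(n_rep)
  if (n_rep < 100) stop("n_rep must be >= 100")
  set.seed(seed)

  p_ab <- matrix(NA_real_, n_rep, length(methods), dimnames = list(NULL, methods))
  p_null <- p_ab
  matched <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ab <- sim_model2(c_amp, v, k = k, l = l, noise_sk = noise_sk,
                     noise_ku = noise_ku)
    nul <- sim_model2(0, v, k = k, l = l, noise_sk = noise_sk,
                      noise_ku = noise_ku)
    for (series_arm in c("ab", "nul")) {
      r <- if (series_arm == "ab") ab$series else nul$series
      scan <- max_t_scan(r, cfg$min_width)
      if (series_arm == "ab") {
        found <- sort(unique(c(if (scan$i > 0L) scan$i,
                               if (scan$j < length(r)) scan$j)))
        truth <- ab$truth$cuts
        matched[i] <- length(truth) > 0 &&
          all(vapply(truth, function(b) any(abs(found - b) <= match_tol),
                     logical(1)))
      }
      for (m in methods) {
        p <- if (m == "gev") {
          params <- model_lookup(model, length(r), noise_sk, noise_ku,
                                 warn_clamp = FALSE)
          gev_p_value(scan$abs_t_max, params)
        } else {
          permutation_p_value(r, scan$abs_t_max, n_perm = n_perm, alpha = 1,
                              early_stop = FALSE,
                              min_width = cfg$min_width)$p_value
        }
        if (series_arm == "ab") p_ab[i, m] <- p else p_null[i, m] <- p
      }
    }
  }

  tab <- do.call(rbind, lapply(methods, function(m) {
    p_eff <- ifelse(matched, p_ab[, m], Inf)
    data.frame(method = m, alpha = alpha_grid,
               sensitivity = vapply(alpha_grid, function(a) mean(p_eff < a),
                                    numeric(1)),
               specificity = vapply(alpha_grid, function(a) mean(p_null[, m] >= a),
                                    numeric(1)),
               stringsAsFactors = FALSE)
  }))
  auc <- vapply(methods, function(m) {
    p_eff <- ifelse(matched, p_ab[, m], Inf)
    # P(aberration ranked more significant than null) + 0.5 ties
    mean(outer(p_eff, p_null[, m], "<")) +
      0.5 * mean(outer(p_eff, p_null[, m], "=="))
  }, numeric(1))
  list(table = tab, auc = auc, p_aberration = p_ab, p_null = p_null,
       matched = matched)
}
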