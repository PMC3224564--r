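#' Run configuration
#'
#' Bundles the tunable thresholds of the segmentation pipeline with their
#' defaults: test level `alpha` (0.01), GEV-lookup minimum segment size
#' `gev_min_probes` (100 probes; shorter segments fall back to permutation),
#' scan `min_width` (2 probes per arc), pre-segmentation small-segment
#' discard `small_segment` (15 probes), edge-correction window `edge_window`
#' (25 probes) and level `edge_alpha` (0.01), permutation budget `n_perm`
#' (10,000) with `early_stop`, the pre-segmentation threshold level
#' `preseg_alpha` (0.001, Bonferroni over arcs) and resolution floor
#' `preseg_min_probes` (100).
#'
#' @param alpha significance level for change-point tests, in (0, 1).
#' @param gev_min_probes minimum probes for the GEV-lookup path.
#' @param min_width minimum probes per arc in the maximal-t scan.
#' @param small_segment pre-segmentation segments shorter than this are
#'   discarded before moment estimation.
#' @param edge_window probes on each side of a boundary used by the
#'   edge-correction t-test.
#' @param edge_alpha level of the edge-correction t-test.
#' @param n_perm permutation budget for the fallback test.
#' @param early_stop stop permutations once p > alpha is guaranteed.
#' @param preseg_alpha family-wise level of the fixed pre-segmentation
#'   threshold.
#' @param preseg_min_probes pre-segmentation recursion floor.
#' @param force_permutation evaluate every candidate by permutation
#'   (validation mode).
#' @param edge_correction apply edge-effect correction.
#' @return A list of class `ecbs_config`.
#' @export
ecbs_config <- function(alpha = 0.01, gev_min_probes = 100L, min_width = 2L,
                        small_segment = 15L, edge_window = 25L,
                        edge_alpha = 0.01, n_perm = 10000L, early_stop = TRUE,
                        preseg_alpha = 0.001, preseg_min_probes = 100L,
                        force_permutation = FALSE, edge_correction = TRUE) {
  cfg <- list(alpha = alpha, gev_min_probes = as.integer(gev_min_probes),
              min_width = as.integer(min_width),
              small_segment = as.integer(small_segment),
              edge_window = as.integer(edge_window), edge_alpha = edge_alpha,
              n_perm = as.integer(n_perm), early_stop = isTRUE(early_stop),
              preseg_alpha = preseg_alpha,
              preseg_min_probes = as.integer(preseg_min_probes),
              force_permutation = isTRUE(force_permutation),
              edge_correction = isTRUE(edge_correction))
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(cfg$edge_alpha > 0 && cfg$edge_alpha < 1)) stop("edge_alpha must lie in (0, 1)")
  with(cfg, stopifnot(gev_min_probes > 0, min_width > 0, small_segment > 0,
                      edge_window > 0, n_perm > 0, preseg_alpha > 0,
                      preseg_min_probes > 0))
  class(cfg) <- "ecbs_config"
  cfg
}

#' GEV-model p-value for a maximal-t statistic
#'
#' `1 - gevcdf(t_max, params)`: the upper-tail probability of the observed
#' maximal-t statistic under the GEV null model; strictly nonincreasing in
#' `t_max`.
#'
#' @param t_max observed maximal-t statistic (callers pass `|T_max|`, the
#'   quantity the null tables model).
#' @param params GEV parameters: a list with `gamma`, `sigma`, `mu`.
#' @return The p-value.
#' @examples
#' gev_p_value(3, list(gamma = 0, sigma = 1, mu = 3))  # 1 - exp(-1)
#' @export
gev_p_value <- function(t_max, params) {
  1 - pgev(t_max, params$gamma, params$sigma, params$mu)
}

#' Permutation p-value for a maximal-t statistic
#'
#' Permutes the series uniformly, recomputes `|T_max|` for each permutation,
#' and returns the add-one estimator `(1 + #exceedances) / (1 + #permutations
#' performed)`.  With `early_stop`, permutation stops as soon as the
#' exceedance count alone guarantees that the final p-value would exceed
#' `alpha`, and the (conservative) estimate from the permutations performed
#' so far is returned; early stopping therefore never changes a decision at
#' level `alpha`.
#'
#' @param r the probe series.
#' @param t_obs observed maximal-t statistic (its absolute value is used).
#' @param n_perm number of permutations (>= 100).
#' @param alpha level used by the early-stopping rule.
#' @param early_stop enable early stopping.
#' @param min_width minimum probes per arc in the scan.
#' @return A list with `p_value`, `exceed` and `n_done`.
#' @export
permutation_p_value <- function(r, t_obs, n_perm = 10000L, alpha = 0.01,
                                early_stop = TRUE, min_width = 2L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100) stop("n_perm must be >= 100")
  r <- as.numeric(r)
  if (!(stats::sd(r) > 0)) stop("degenerate series: sample standard deviation is zero")
  .perm_tmax_cpp(r, abs(t_obs), n_perm, as.integer(min_width), alpha,
                 isTRUE(early_stop))
}

#' Evaluate the significance of a candidate change-point pair
#'
#' Routes a scanned segment to the GEV table-lookup test when it has at
#' least `gev_min_probes` probes (default 100, boundary inclusive), and to
#' the permutation test with early stopping otherwise.  `sk` and `ku` are
#' the array-level noise-moment estimates from pre-segmentation.
#'
#' @param r the probe series of the segment under test.
#' @param scan result of [max_t_scan()] on `r`.
#' @param model an `ecbs_model`.
#' @param sk,ku array-level noise skewness and kurtosis estimates.
#' @param cfg an [ecbs_config()].
#' @return A list of class `ecbs_significance` with `p_value`, `method`
#'   (`"gev_lookup"` or `"permutation"`), `t_max`, `alpha`, `significant`,
#'   and the candidate indices `i`, `j`.
#' @export
evaluate_significance <- function(r, scan, model, sk, ku, cfg = ecbs_config()) {
  n <- length(r)
  if (!cfg$force_permutation && n >= cfg$gev_min_probes) {
    params <- model_lookup(model, n, sk, ku, warn_clamp = FALSE)
    p <- gev_p_value(scan$abs_t_max, params)
    method <- "gev_lookup"
  } else {
    perm <- permutation_p_value(r, scan$abs_t_max, n_perm = cfg$n_perm,
                                alpha = cfg$alpha, early_stop = cfg$early_stop,
                                min_width = cfg$min_width)
    p <- perm$p_value
    method <- "permutation"
  }
  structure(list(p_value = p, method = method, t_max = scan$t_max,
                 alpha = cfg$alpha, significant = p < cfg$alpha,
                 i = scan$i, j = scan$j, n = n),
            class = "ecbs_significance")
}
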