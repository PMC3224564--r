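# Welch two-sample t-test p-value that tolerates zero-variance windows
# (noise-free data): with both windows constant, the boundary survives
# exactly when the means differ.
welch_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) return(1)
  v1 <- if (n1 > 1) stats::var(a) else 0
  v2 <- if (n2 > 1) stats::var(b) else 0
  if (v1 == 0 && v2 == 0) return(if (mean(a) == mean(b)) 1 else 0)
  if (n1 < 2 || n2 < 2) return(1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  if (!is.finite(df) || df <= 0) return(1)
  2 * stats::pt(-abs(tt), df)
}

#' Edge-effect correction of candidate boundaries
#'
#' Circularly joining a segment's ends can make the maximal-t scan place a
#' boundary where no mean shift exists.  Each candidate boundary is
#' re-tested by a two-sample (Welch) t-test comparing the `edge_window`
#' probes on either side, capped at the lengths of the adjacent proposed
#' subsegments; boundaries failing at `edge_alpha` are dropped.  If every
#' boundary fails, the split is rejected (empty result).
#'
#' @param r the probe series of the segment under test.
#' @param cuts candidate cut points (probe indices; a cut at `b` separates
#'   probes `b` and `b + 1`).
#' @param cfg an [ecbs_config()].
#' @return The surviving cut points (possibly empty).
#' @export
edge_correct <- function(r, cuts, cfg = ecbs_config()) {
  n <- length(r)
  cuts <- sort(unique(as.integer(cuts)))
  if (!length(cuts)) return(integer(0))
  if (any(cuts < 1L | cuts >= n)) stop("cut points must lie in 1..N-1")
  bounds <- c(0L, cuts, n)
  keep <- logical(length(cuts))
  for (ci in seq_along(cuts)) {
    b <- cuts[ci]
    wl <- min(cfg$edge_window, b - bounds[ci])
    wr <- min(cfg$edge_window, bounds[ci + 2L] - b)
    left <- r[(b - wl + 1L):b]
    right <- r[(b + 1L):(b + wr)]
    keep[ci] <- welch_p(left, right) < cfg$edge_alpha
  }
  cuts[keep]
}

#' Recursive change-point detection for one chromosome
#'
#' The segmentation engine: recursively (1) locates the candidate
#' change-point pair by exhaustive circular maximal-t scan, (2) evaluates
#' its significance through the eXtreme model (or the permutation fallback
#' for segments shorter than `gev_min_probes`), (3) applies edge-effect
#' correction to the proposed boundaries, and (4) splits into up to three
#' subsegments at the surviving boundaries, recursing on each.  The
#' maximal-t statistic is always computed from the original data of the
#' segment under test (re-standardized within the segment), never from
#' pre-segmented data; the noise profile, in contrast, is estimated once per
#' array beforehand.
#'
#' Recursion ends when a segment's test is not significant, its proposed
#' split is rejected by edge correction, it is shorter than
#' `2 * min_width`, or it has zero variance.
#'
#' @param r numeric vector: the chromosome's probe log2 ratios.
#' @param profile an `ecbs_noise_profile` (see [estimate_noise_moments()]),
#'   estimated from the original array data.
#' @param model an `ecbs_model`.
#' @param cfg an [ecbs_config()].
#' @return A data.frame tiling `1..N`: `start_index`, `end_index`,
#'   `n_probes`, `seg_mean`, `p_value` (the p-value of the split that
#'   created the segment; `NA` for segments never produced by a split) and
#'   `method` of that test.
#' @export
find_change_points <- function(r, profile, model, cfg = ecbs_config()) {
  r <- as.numeric(r)
  if (anyNA(r) || any(!is.finite(r))) stop("series contains non-finite values")
  segs <- list()
  emit <- function(lo, hi, p, method) {
    segs[[length(segs) + 1L]] <<- data.frame(
      start_index = lo, end_index = hi, n_probes = hi - lo + 1L,
      seg_mean = mean(r[lo:hi]), p_value = p, method = method,
      stringsAsFactors = FALSE)
  }
  recurse <- function(lo, hi, p_created, method_created) {
    n <- hi - lo + 1L
    if (n < 2L * cfg$min_width) return(emit(lo, hi, p_created, method_created))
    sub <- r[lo:hi]
    if (!(stats::sd(sub) > 0)) return(emit(lo, hi, p_created, method_created))
    scan <- max_t_scan(sub, cfg$min_width)
    sig <- evaluate_significance(sub, scan, model, profile$sk, profile$ku, cfg)
    if (!sig$significant) return(emit(lo, hi, p_created, method_created))
    local_cuts <- sort(unique(c(if (scan$i > 0L) scan$i,
                                if (scan$j < n) scan$j)))
    if (cfg$edge_correction) local_cuts <- edge_correct(sub, local_cuts, cfg)
    if (!length(local_cuts)) return(emit(lo, hi, p_created, method_created))
    bounds <- c(lo - 1L, lo - 1L + local_cuts, hi)
    for (b in seq_len(length(bounds) - 1L))
      recurse(bounds[b] + 1L, bounds[b + 1L], sig$p_value, sig$method)
    invisible()
  }
  recurse(1L, length(r), NA_real_, NA_character_)
  out <- do.call(rbind, segs)
  out <- out[order(out$start_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment an aCGH probe table
#'
#' End-to-end segmentation of one or more samples: for each sample, the
#' noise skewness and kurtosis are estimated once across its chromosomes by
#' pre-segmentation ([estimate_noise_moments()]), then each chromosome is
#' segmented by [find_change_points()] against the eXtreme model.
#'
#' @param probes a probe table from [read_probe_table()] (columns `sample`,
#'   `chrom`, `position`, `log2ratio`).
#' @param model an `ecbs_model`.
#' @param cfg an [ecbs_config()].
#' @param profile optional: a fixed noise profile (skips per-sample
#'   estimation; mainly for simulations where the noise moments are known).
#' @return A data.frame of class `ecbs_segments` with columns `sample`,
#'   `chrom`, `start_index`, `end_index`, `start_pos`, `end_pos`,
#'   `n_probes`, `seg_mean`, `p_value`, `method`.  Per-sample noise profiles
#'   are attached as attribute `"profiles"`.
#' @export
segment_probes <- function(probes, model, cfg = ecbs_config(), profile = NULL) {
  stopifnot(is.data.frame(probes),
            all(c("sample", "chrom", "position", "log2ratio") %in% names(probes)))
  groups <- probe_series_list(probes)
  samples <- unique(vapply(groups, function(g) g$sample[1], character(1)))
  profiles <- list()
  out <- list()
  for (smp in samples) {
    smp_groups <- Filter(function(g) g$sample[1] == smp, groups)
    prof <- if (is.null(profile)) {
      estimate_noise_moments(lapply(smp_groups, `[[`, "log2ratio"), cfg)
    } else profile
    profiles[[smp]] <- prof
    for (g in smp_groups) {
      r <- g$log2ratio
      if (length(r) < 2L * cfg$min_width) {
        warning(sprintf("sample %s chrom %s: only %d probe(s); emitted as a single segment",
                        smp, g$chrom[1], length(r)))
        segs <- data.frame(start_index = 1L, end_index = length(r),
                           n_probes = length(r), seg_mean = mean(r),
                           p_value = NA_real_, method = NA_character_,
                           stringsAsFactors = FALSE)
      } else {
        segs <- find_change_points(r, prof, model, cfg)
      }
      segs$sample <- smp
      segs$chrom <- g$chrom[1]
      segs$start_pos <- g$position[segs$start_index]
      segs$end_pos <- g$position[segs$end_index]
      out[[length(out) + 1L]] <- segs
    }
  }
  res <- do.call(rbind, out)
  res <- res[, c("sample", "chrom", "start_index", "end_index", "start_pos",
                 "end_pos", "n_probes", "seg_mean", "p_value", "method")]
  rownames(res) <- NULL
  attr(res, "profiles") <- profiles
  class(res) <- c("ecbs_segments", "data.frame")
  res
}
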