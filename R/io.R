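#' Read a probe-level aCGH table
#'
#' Reads a tab-delimited probe table with header columns `sample`, `chrom`,
#' `position`, `log2ratio` and optionally `snr`.  Rows with missing position
#' or non-finite log2 ratio are dropped; when an `snr` column is present and
#' the filter is enabled, probes with signal-to-noise ratio below
#' `snr_threshold` are dropped (default threshold 1).  Probes are sorted by
#' position within each chromosome; drop counts are logged.  Probes sharing
#' a position are kept as-is and flagged in the log.
#'
#' @param path path to the tab-delimited file.
#' @param snr_filter apply the SNR filter when an `snr` column is present.
#' @param snr_threshold minimum SNR kept (default 1).
#' @return A `data.frame` of class `ecbs_probes`, sorted by sample,
#'   chromosome (natural order: 1-22, X, Y, then lexicographic) and position.
#' @export
read_probe_table <- function(path, snr_filter = TRUE, snr_threshold = 1) {
  if (!file.exists(path)) stop("probe file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = "character"),
    error = function(e) stop("unparseable probe file '", path, "': ",
                             conditionMessage(e)))
  required <- c("sample", "chrom", "position", "log2ratio")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("probe file format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))

  pos <- suppressWarnings(as.numeric(df$position))
  ratio <- suppressWarnings(as.numeric(df$log2ratio))
  bad_pos <- is.na(pos) | pos < 1
  bad_ratio <- !is.finite(ratio)
  n_drop <- sum(bad_pos | bad_ratio)
  keep <- !(bad_pos | bad_ratio)
  if (n_drop > 0)
    ecbs_log("read_probe_table: dropped %d row(s) with missing position or non-finite ratio",
             n_drop)

  snr_dropped <- 0L
  if (snr_filter && "snr" %in% names(df)) {
    snr <- suppressWarnings(as.numeric(df$snr))
    low <- !is.na(snr) & snr < snr_threshold
    snr_dropped <- sum(low & keep)
    keep <- keep & !low
    if (snr_dropped > 0)
      ecbs_log("read_probe_table: dropped %d probe(s) with SNR < %g",
               snr_dropped, snr_threshold)
  }

  out <- data.frame(sample = df$sample[keep], chrom = df$chrom[keep],
                    position = as.integer(pos[keep]),
                    log2ratio = ratio[keep], stringsAsFactors = FALSE)
  if (nrow(out) == 0) warning("no probes left after filtering")
  out <- out[order(out$sample, chrom_rank(out$chrom), out$chrom, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  dup <- duplicated(out[c("sample", "chrom", "position")])
  if (any(dup))
    ecbs_log("read_probe_table: %d probe(s) share a genomic position with another probe (kept as-is)",
             sum(dup))
  class(out) <- c("ecbs_probes", "data.frame")
  out
}

# natural chromosome order: 1..22, X, Y, then everything else alphabetically
chrom_rank <- function(chrom) {
  key <- toupper(sub("^chr", "", chrom, ignore.case = TRUE))
  r <- match(key, c(as.character(1:22), "X", "Y"))
  r[is.na(r)] <- 25L
  r
}

# split a probe table into per-(sample, chrom) series, natural order
probe_series_list <- function(probes) {
  idx <- order(probes$sample, chrom_rank(probes$chrom), probes$chrom,
               probes$position)
  probes <- probes[idx, , drop = FALSE]
  key <- paste(probes$sample, probes$chrom, sep = "\r")
  split(probes, factor(key, levels = unique(key)))
}

#' Write segmentation results
#'
#' Writes a SEG-style tab-delimited table with columns `sample`, `chrom`,
#' `start_pos`, `end_pos`, `n_probes`, `seg_mean`, `p_value` in deterministic
#' order (sample, chromosome in natural order, start position).  Absent
#' p-values are emitted as `NA`.  Segments of each chromosome must tile its
#' probes without overlap.
#'
#' @param segments a segment table as returned by [segment_probes()].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_segments <- function(segments, path) {
  required <- c("sample", "chrom", "start_pos", "end_pos", "n_probes", "seg_mean")
  if (!all(required %in% names(segments)))
    stop("segment table is missing column(s): ",
         paste(setdiff(required, names(segments)), collapse = ", "))
  if (!"p_value" %in% names(segments)) segments$p_value <- NA_real_
  check_tiling(segments)
  ord <- order(segments$sample, chrom_rank(segments$chrom), segments$chrom,
               segments$start_pos)
  out <- segments[ord, c("sample", "chrom", "start_pos", "end_pos",
                         "n_probes", "seg_mean", "p_value"), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

check_tiling <- function(segments) {
  if (all(c("start_index", "end_index") %in% names(segments))) {
    by <- paste(segments$sample, segments$chrom, sep = "\r")
    for (grp in split(seq_len(nrow(segments)), by)) {
      s <- segments[grp, , drop = FALSE]
      s <- s[order(s$start_index), , drop = FALSE]
      if (any(s$end_index < s$start_index))
        stop("invalid segment: end_index < start_index")
      if (any(s$n_probes != s$end_index - s$start_index + 1))
        stop("invalid segment: n_probes inconsistent with index range")
      if (nrow(s) > 1 && any(s$start_index[-1] != s$end_index[-nrow(s)] + 1))
        stop("segments overlap or leave gaps within a chromosome")
      if (s$start_index[1] != 1)
        stop("segments do not start at probe 1")
    }
  }
  invisible(TRUE)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load an eXtreme model
#'
#' The model is serialized as a single versioned JSON document carrying the
#' three grid axes, the three GEV parameter tables (flattened, with
#' dimensions), the per-cell convergence flags and the build metadata
#' (replicate count, build seed, scan minimum width).  Numbers are written at
#' full precision, so `load_model(save_model(m))` reproduces every axis and
#' parameter value bit-exactly.
#'
#' @param model an object of class `ecbs_model` (see [build_model()]).
#' @param path file path for the JSON document.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   `ecbs_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ecbs_model"))
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    n_axis = model$n_axis,
    sk_axis = model$sk_axis,
    ku_axis = model$ku_axis,
    dim = dim(model$gamma),
    gamma = as.vector(model$gamma),
    sigma = as.vector(model$sigma),
    mu = as.vector(model$mu),
    converged = as.vector(model$converged),
    replicates_per_cell = model$replicates_per_cell,
    build_seed = model$build_seed,
    scan_min_width = model$scan_min_width
  )
  # digits = I(17) emits significant digits, enough for doubles to
  # round-trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("truncated or corrupt model file '",
                                           path, "': ", conditionMessage(e)))
  if (is.null(doc$format_version))
    stop("model file is missing its format_version")
  if (doc$format_version != MODEL_FORMAT_VERSION)
    stop(sprintf("model format version mismatch: file has %s, this build reads %d",
                 doc$format_version, MODEL_FORMAT_VERSION))
  for (comp in c("n_axis", "sk_axis", "ku_axis", "dim", "gamma", "sigma", "mu",
                 "replicates_per_cell"))
    if (is.null(doc[[comp]]))
      stop("model file is missing component '", comp, "'")
  d <- as.integer(doc$dim)
  model <- structure(list(
    n_axis = as.numeric(doc$n_axis),
    sk_axis = as.numeric(doc$sk_axis),
    ku_axis = as.numeric(doc$ku_axis),
    gamma = array(as.numeric(doc$gamma), d),
    sigma = array(as.numeric(doc$sigma), d),
    mu = array(as.numeric(doc$mu), d),
    converged = array(if (is.null(doc$converged)) TRUE else as.logical(doc$converged), d),
    replicates_per_cell = as.integer(doc$replicates_per_cell),
    build_seed = if (is.null(doc$build_seed)) NA_integer_ else as.integer(doc$build_seed),
    scan_min_width = if (is.null(doc$scan_min_width)) 2L else as.integer(doc$scan_min_width)
  ), class = "ecbs_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  for (ax in c("n_axis", "sk_axis", "ku_axis")) {
    v <- model[[ax]]
    if (length(v) < 1 || is.unsorted(v, strictly = TRUE))
      stop("model axis '", ax, "' must be strictly increasing")
  }
  d <- c(length(model$n_axis), length(model$sk_axis), length(model$ku_axis))
  for (tab in c("gamma", "sigma", "mu"))
    if (!identical(dim(model[[tab]]), as.integer(d)))
      stop("model table '", tab, "' has wrong dimensions")
  if (any(!(model$sigma > 0)))
    stop("model contains non-positive sigma entries")
  invisible(TRUE)
}
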