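# Lazily built, memoized models shared across test files (helpers are loaded
# once per test run, so each model is built at most once per session).

.model_cache <- new.env(parent = emptyenv())

cached_model <- function(name, builder) {
  if (is.null(.model_cache[[name]])) .model_cache[[name]] <- builder()
  .model_cache[[name]]
}

# small model for unit tests of lookup/segmentation plumbing
tiny_model <- function() {
  cached_model("tiny", function() {
    build_model(list(n_axis = c(100, 150, 250), sk_axis = c(-0.2, 0, 0.2),
                     ku_axis = c(2.6, 3.0, 3.4)),
                replicates = 500, seed = 101)
  })
}

# calibration-grade model for the normal-noise acceptance checks; the sk/ku
# axes are wide enough to track per-array moment estimates at N >= 100
calib_model <- function() {
  cached_model("calib", function() {
    build_model(list(n_axis = c(100, 150, 250, 1000),
                     sk_axis = c(-0.4, -0.2, 0, 0.2, 0.4),
                     ku_axis = c(2.6, 3.0, 3.4, 3.8)),
                replicates = 4000, seed = 202)
  })
}

# single-N model around the skewed/heavy-tailed ROC operating point
roc_model <- function() {
  cached_model("roc", function() {
    build_model(list(n_axis = 1500, sk_axis = c(0.3, 0.5, 0.7),
                     ku_axis = c(3.5, 4.0, 4.5)),
                replicates = 2000, seed = 303)
  })
}

known_normal_profile <- function() {
  structure(list(sk = 0, ku = 3, n_probes_used = NA_integer_,
                 n_segments_removed = 0L, fallback = FALSE),
            class = "ecbs_noise_profile")
}
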