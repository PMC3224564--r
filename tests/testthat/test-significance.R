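test_that("GEV p-values follow the closed form and decrease in t", {
  gumbel <- list(gamma = 0, sigma = 1, mu = 3)
  expect_equal(gev_p_value(3, gumbel), 1 - exp(-1))
  expect_equal(gev_p_value(1e9, gumbel), 0)
  t <- seq(0, 12, length.out = 200)
  p <- vapply(t, gev_p_value, numeric(1), params = list(gamma = 0.1, sigma = 0.4, mu = 3.2))
  expect_true(all(diff(p) <= 0))
})

test_that("permutation p-value honors the add-one estimator bounds", {
  set.seed(1)
  r <- rnorm(60)
  # t_obs = 0: every permutation exceeds
  res <- permutation_p_value(r, 0, n_perm = 200, early_stop = FALSE)
  expect_equal(res$p_value, 1)
  # t_obs above everything: p = 1/(n_perm + 1)
  res <- permutation_p_value(r, 99, n_perm = 999, early_stop = FALSE)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$exceed, 0L)
})

test_that("a strong step is significant in (almost) every seeded run", {
  hits <- 0L
  for (seed in 1:30) {
    set.seed(seed)
    r <- c(rep(0, 30), rep(2, 30)) + rnorm(60)
    scan <- max_t_scan(r)
    p <- permutation_p_value(r, scan$abs_t_max, n_perm = 1000,
                             early_stop = FALSE)$p_value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 29L)
})

test_that("early stopping only fires on clearly null cases and never flips a decision", {
  for (seed in 1:25) {
    set.seed(seed)
    r <- rnorm(80)
    scan <- max_t_scan(r)
    set.seed(seed + 1000)
    full <- permutation_p_value(r, scan$abs_t_max, n_perm = 500, alpha = 0.05,
                                early_stop = FALSE)
    set.seed(seed + 1000)
    early <- permutation_p_value(r, scan$abs_t_max, n_perm = 500, alpha = 0.05,
                                 early_stop = TRUE)
    if (full$p_value <= 0.05) {
      expect_identical(early, full)  # never stopped early
    } else {
      expect_gt(early$p_value, 0.05)  # conservative estimate agrees on H0
    }
  }
})

test_that("evaluate routes by segment size with an inclusive 100-probe boundary", {
  m <- tiny_model()
  cfg <- ecbs_config(n_perm = 200)
  set.seed(2)
  for (n in c(250, 100, 60)) {
    r <- rnorm(n)
    sig <- evaluate_significance(r, max_t_scan(r), m, 0, 3, cfg)
    expect_identical(sig$method, if (n >= 100) "gev_lookup" else "permutation")
    expect_identical(sig$significant, sig$p_value < cfg$alpha)
  }
  # forced permutation overrides the routing
  r <- rnorm(250)
  sig <- evaluate_significance(r, max_t_scan(r), m, 0, 3,
                               ecbs_config(n_perm = 200, force_permutation = TRUE))
  expect_identical(sig$method, "permutation")
})
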