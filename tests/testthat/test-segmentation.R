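test_that("noise moments are recovered from clean noise and unaffected by a CNA shift", {
  set.seed(101)
  x <- rnorm(2000)
  prof <- estimate_noise_moments(x)
  expect_lt(abs(prof$sk - 0), 0.1)
  expect_lt(abs(prof$ku - 3), 0.2)

  # a strong 300-probe amplification (+3 sd) leaves the pre-segmented
  # estimates unchanged...
  shifted <- x
  shifted[501:800] <- shifted[501:800] + 3.0
  prof2 <- estimate_noise_moments(shifted)
  expect_lt(abs(prof2$sk - 0), 0.1)
  expect_lt(abs(prof2$ku - 3), 0.2)
  # ...whereas naive whole-array moments are badly biased by it
  # (mixture theory: sk ~ 0.77, ku inflated by ~ 0.5 over the clean noise)
  naive <- sample_sk_ku(shifted)
  clean <- sample_sk_ku(x)
  expect_gt(naive["ku"] - clean["ku"], 0.3)
  expect_gt(abs(naive["sk"] - clean["sk"]), 0.5)
})

test_that("degenerate and short inputs fall back with a warning", {
  w <- capture_warnings(p <- estimate_noise_moments(rep(0.3, 500)))
  expect_match(w, "constant|fallback", all = FALSE)
  expect_identical(c(p$sk, p$ku), c(0, 3))
  set.seed(1)
  expect_warning(p2 <- estimate_noise_moments(rnorm(150)), "fewer than 200")
  expect_true(p2$fallback)
  expect_lt(abs(p2$ku - 3), 0.7)
})

test_that("estimates are clamped to the simulation grid ranges", {
  set.seed(7)
  # exponential noise: sk = 2, ku = 9, far outside the grid
  x <- rexp(3000) - 1
  prof <- estimate_noise_moments(x)
  expect_lte(prof$sk, 1)
  expect_lte(prof$ku, 5.6)
  expect_gte(prof$ku, prof$sk^2 + 1)
})

test_that("edge correction keeps real boundaries and prunes flat ones", {
  cfg <- ecbs_config()
  r <- c(rep(0, 50), rep(2, 30), rep(2, 20))
  # cut at 50 separates different means; cut at 80 separates equal means
  expect_identical(edge_correct(r, c(50L, 80L), cfg), 50L)
  set.seed(3)
  rn <- r + rnorm(100, 0, 0.2)
  expect_identical(edge_correct(rn, c(50L, 80L), cfg), 50L)
  # both boundaries flat: the split is rejected entirely
  set.seed(4)
  expect_length(edge_correct(rep(0.5, 100) + rnorm(100, 0, 1e-3), c(30L, 60L), cfg), 0)
})

test_that("a noiseless multi-segment series is segmented exactly", {
  r <- c(rep(0, 49), rep(2, 20), rep(-2, 10), rep(2, 20), rep(0, 51))
  set.seed(5)
  segs <- find_change_points(r, known_normal_profile(), tiny_model(),
                             ecbs_config(n_perm = 500))
  expect_equal(nrow(segs), 5)
  expect_equal(segs$end_index[-5], c(49, 69, 79, 99))
  expect_equal(segs$seg_mean, c(0, 2, -2, 2, 0))
  # tiling invariants
  expect_equal(segs$start_index[1], 1)
  expect_equal(segs$start_index[-1], segs$end_index[-5] + 1)
  expect_equal(sum(segs$n_probes), length(r))
})

test_that("segmentation output always tiles the input and is seed-deterministic", {
  m <- tiny_model()
  cfg <- ecbs_config(n_perm = 300)
  for (seed in 1:8) {
    set.seed(seed)
    sim <- sim_model1(c_amp = 3)
    set.seed(seed + 500)
    segs <- find_change_points(sim$series, known_normal_profile(), m, cfg)
    expect_equal(segs$start_index[1], 1)
    expect_equal(segs$end_index[nrow(segs)], 150)
    expect_equal(sum(segs$n_probes), 150)
    if (nrow(segs) > 1)
      expect_equal(segs$start_index[-1], segs$end_index[-nrow(segs)] + 1)
    set.seed(seed + 500)
    segs2 <- find_change_points(sim$series, known_normal_profile(), m, cfg)
    expect_identical(segs, segs2)
  }
})

test_that("pure null series are rarely split at alpha = 0.01", {
  m <- tiny_model()
  cfg <- ecbs_config(n_perm = 300)
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    r <- rnorm(250)
    segs <- find_change_points(r, known_normal_profile(), m, cfg)
    if (nrow(segs) > 1) hits <- hits + 1L
  }
  expect_lte(hits, 3L)
})

test_that("detection of an embedded segment is monotone in amplitude", {
  m <- tiny_model()
  cfg <- ecbs_config(n_perm = 300)
  rate <- vapply(c(1, 2, 3, 4), function(c_amp) {
    det <- 0L
    for (seed in 1:25) {
      set.seed(7000 + seed)
      v <- 0.25
      r <- rnorm(250, 0, v)
      r[101:115] <- r[101:115] + c_amp * v  # 15-probe aberration
      scan <- max_t_scan(r)
      sig <- evaluate_significance(r, scan, m, 0, 3, cfg)
      if (sig$significant) det <- det + 1L
    }
    det / 25
  }, numeric(1))
  expect_true(all(diff(rate) >= -0.04))
  expect_gt(rate[4], rate[1])
})

test_that("segment_probes runs end-to-end and round-trips through SEG files", {
  m <- tiny_model()
  set.seed(11)
  sim <- sim_model1(c_amp = 4)
  probes <- data.frame(sample = "s1", chrom = "1",
                       position = seq_len(150) * 1000L,
                       log2ratio = sim$series)
  set.seed(12)
  segs <- segment_probes(probes, m, ecbs_config(n_perm = 300),
                         profile = known_normal_profile())
  expect_s3_class(segs, "ecbs_segments")
  expect_equal(sum(segs$n_probes), 150)
  expect_equal(segs$start_pos[1], 1000L)
  path <- withr::local_tempfile(fileext = ".seg")
  write_segments(segs, path)
  out <- read.delim(path)
  expect_equal(nrow(out), nrow(segs))
})
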