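test_that("t_statistic matches hand evaluation and is antisymmetric", {
  r <- c(0, 0, 0, 1, 1, 1)
  expect_equal(t_statistic(r, 3, 6), 2.236068, tolerance = 1e-6)
  expect_equal(t_statistic(r, 0, 3), -2.236068, tolerance = 1e-6)
  # complementary arcs negate each other on random data too
  set.seed(4)
  x <- rnorm(20)
  expect_equal(t_statistic(x, 0, 7), -t_statistic(x, 7, 20))
})

test_that("t_statistic rejects degenerate and out-of-domain input", {
  expect_error(t_statistic(rep(1, 10), 2, 5), "degenerate")
  expect_error(t_statistic(rnorm(10), 5, 5), "i < j")
  expect_error(t_statistic(rnorm(10), 0, 10), "arc width")
  expect_error(t_statistic(rnorm(10), -1, 3), "i < j")
})

test_that("|T| is invariant to location and positive scale", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rnorm(sample(10:50, 1))
    i <- 0; j <- sample(2:(length(x) - 2), 1)
    a <- runif(1, 0.1, 5); b <- runif(1, -3, 3)
    expect_equal(abs(t_statistic(a * x + b, i, j)), abs(t_statistic(x, i, j)),
                 tolerance = 1e-10)
  }
})

test_that("max_t_scan equals the brute-force oracle", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    x <- rnorm(n)
    got <- max_t_scan(x)
    want <- brute_force_scan(x)
    expect_equal(got$abs_t_max, want$abs_t_max, tolerance = 1e-12)
    # reported indices attain the maximum
    expect_equal(abs(t_statistic(x, got$i, got$j)), want$abs_t_max,
                 tolerance = 1e-12)
  }
})

test_that("scan tie-break picks the lexicographically smallest pair", {
  got <- max_t_scan(c(0, 0, 0, 1, 1, 1))
  expect_equal(got$abs_t_max, 2.236068, tolerance = 1e-6)
  expect_equal(c(got$i, got$j), c(0, 3))
})

test_that("a clean step is located exactly", {
  r <- c(rep(0, 50), rep(3, 50))
  got <- max_t_scan(r)
  expect_true(identical(c(got$i, got$j), c(0L, 50L)) ||
                identical(c(got$i, got$j), c(50L, 100L)))
  # lexicographic tie-break of the complementary representations
  expect_equal(c(got$i, got$j), c(0, 50))
})

test_that("|T_max| is invariant under circular shifts", {
  set.seed(31)
  for (rep in 1:15) {
    x <- rnorm(40)
    base <- max_t_scan(x)$abs_t_max
    sh <- sample(length(x) - 1, 1)
    rot <- c(x[-seq_len(sh)], x[seq_len(sh)])
    expect_equal(max_t_scan(rot)$abs_t_max, base, tolerance = 1e-10)
  }
})

test_that("scan enforces width preconditions", {
  expect_error(max_t_scan(rnorm(3), min_width = 2), "too short")
  expect_error(max_t_scan(rep(0.5, 30)), "degenerate")
  expect_error(max_t_scan(c(rnorm(5), NA, rnorm(5))), "non-finite")
})
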