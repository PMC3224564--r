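test_that("toy builds have the right shape, positive scales, and are deterministic", {
  grid <- list(n_axis = c(100, 150), sk_axis = c(0, 0.2), ku_axis = c(3.0, 3.4))
  m1 <- build_model(grid, replicates = 200, seed = 7)
  expect_identical(dim(m1$gamma), c(2L, 2L, 2L))
  expect_true(all(m1$sigma > 0))
  expect_true(all(m1$converged))
  m2 <- build_model(grid, replicates = 200, seed = 7)
  expect_identical(m1$gamma, m2$gamma)
  expect_identical(m1$mu, m2$mu)
  m3 <- build_model(grid, replicates = 200, seed = 8)
  expect_false(identical(m1$gamma, m3$gamma))
})

test_that("build rejects bad grids and replicate counts", {
  expect_error(build_model(list(n_axis = c(100, 100), sk_axis = 0, ku_axis = 3),
                           replicates = 200), "strictly increasing")
  expect_error(build_model(micro_grid(), replicates = 50), ">= 100")
  expect_error(build_model(list(n_axis = 100, sk_axis = 1, ku_axis = 1.5),
                           replicates = 200), "infeasible")
})

test_that("lookup: grid points bit-exact, midpoints are neighbor means, clamping warns", {
  m <- tiny_model()
  # exact grid point
  lk <- model_lookup(m, 150, 0, 3.0)
  expect_identical(lk$gamma, m$gamma[2, 2, 2])
  expect_identical(lk$sigma, m$sigma[2, 2, 2])
  expect_identical(lk$mu, m$mu[2, 2, 2])
  # midway on the sk axis only
  mid <- model_lookup(m, 150, 0.1, 3.0)
  expect_equal(mid$mu, (m$mu[2, 2, 2] + m$mu[2, 3, 2]) / 2)
  expect_equal(mid$gamma, (m$gamma[2, 2, 2] + m$gamma[2, 3, 2]) / 2)
  # off-grid high sk clamps to the boundary
  expect_warning(hi <- model_lookup(m, 150, 1.5, 3.0), "clamped")
  expect_identical(hi$mu, model_lookup(m, 150, 0.2, 3.0)$mu)
  expect_silent(model_lookup(m, 150, 1.5, 3.0, warn_clamp = FALSE))
})

test_that("interpolated values stay inside the convex hull of the 8 neighbors", {
  m <- tiny_model()
  set.seed(19)
  for (rep in 1:25) {
    n <- runif(1, 100, 250); sk <- runif(1, -0.2, 0.2); ku <- runif(1, 2.6, 3.4)
    lk <- model_lookup(m, n, sk, ku)
    ni <- findInterval(n, m$n_axis, rightmost.closed = TRUE)
    si <- findInterval(sk, m$sk_axis, rightmost.closed = TRUE)
    ki <- findInterval(ku, m$ku_axis, rightmost.closed = TRUE)
    for (tab in c("gamma", "sigma", "mu")) {
      nb <- m[[tab]][ni:min(ni + 1, 3), si:min(si + 1, 3), ki:min(ki + 1, 3)]
      expect_gte(lk[[tab]], min(nb) - 1e-12)
      expect_lte(lk[[tab]], max(nb) + 1e-12)
    }
  }
})

test_that("model content varies smoothly along each axis", {
  # relative jumps between adjacent cells stay moderate (supports linear
  # interpolation between grid points)
  m <- calib_model()
  rel_jump <- function(v) abs(diff(v)) / pmax(abs(v[-length(v)]), 0.1)
  for (tab in c("sigma", "mu")) {
    along_sk <- apply(m[[tab]], c(1, 3), function(v) max(rel_jump(v)))
    along_ku <- apply(m[[tab]], c(1, 2), function(v) max(rel_jump(v)))
    expect_lt(max(along_sk), 0.25)
    expect_lt(max(along_ku), 0.25)
  }
})

test_that("serialization round-trips bit-exactly and validates its input", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$gamma, m2$gamma)
  expect_identical(m$sigma, m2$sigma)
  expect_identical(m$mu, m2$mu)
  expect_identical(m$n_axis, m2$n_axis)
  expect_identical(m$replicates_per_cell, m2$replicates_per_cell)

  # version mismatch
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$format_version <- 99L
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, digits = I(17))
  expect_error(load_model(bad), "version mismatch")

  # missing component named in the error
  doc2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc2$mu <- NULL
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc2, bad2, digits = I(17))
  expect_error(load_model(bad2), "'mu'")

  # truncated file
  txt <- readLines(path)
  bad3 <- withr::local_tempfile(fileext = ".json")
  writeLines(txt[1:(length(txt) %/% 2)], bad3)
  expect_error(load_model(bad3), "truncated|corrupt")
})
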