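# The contrast -> flow -> ROI chain against brute-force and closed-form
# oracles.

test_that("sliding-window contrast equals the brute-force double loop", {
  set.seed(101)
  for (d in list(c(8, 8), c(16, 9), c(33, 21))) {
    f <- matrix(sample(1:255, prod(d), replace = TRUE), d[1], d[2])
    storage.mode(f) <- "double"
    k <- spatial_contrast(f)
    expect_equal(k$values, brute_contrast(f), tolerance = 1e-12)
  }
})

test_that("a constant frame has zero contrast everywhere", {
  k <- spatial_contrast(matrix(7, 12, 12))
  expect_true(all(k$values == 0))
  expect_true(all(k$mask))
})

test_that("contrast is invariant to intensity scaling", {
  set.seed(7)
  f <- matrix(rexp(20 * 20) + 0.1, 20)
  k1 <- spatial_contrast(f)$values
  for (c in c(1e-6, 3, 1e8)) {
    expect_equal(spatial_contrast(c * f)$values, k1, tolerance = 1e-12)
  }
})

test_that("window geometry is validated", {
  f <- matrix(1, 10, 10)
  expect_error(spatial_contrast(f, window_px = 4), "odd")
  expect_error(spatial_contrast(matrix(1, 3, 3), window_px = 5), "smaller")
})

test_that("an all-zero frame yields a fully masked map with a warning", {
  expect_warning(k <- spatial_contrast(matrix(0, 10, 10)), "masked")
  expect_true(all(is.na(k$values)))
  expect_false(any(k$mask))
})

test_that("averaging contrast maps is the element-wise mean", {
  f <- matrix(rexp(64), 8)
  one <- spatial_contrast(f)
  # idempotence on identical maps
  avg <- average_contrast(rep(list(one), 25))
  expect_equal(avg$values, one$values, tolerance = 1e-12)
  # arithmetic-mean oracle on constant maps 1..25
  maps <- lapply(1:25, function(i) {
    m <- one
    m$values[] <- i
    m
  })
  expect_true(all(average_contrast(maps)$values == 13))
})

test_that("averaging rejects shape mismatches and short lists", {
  a <- spatial_contrast(matrix(rexp(64), 8))
  b <- spatial_contrast(matrix(rexp(100), 10))
  expect_error(average_contrast(c(rep(list(a), 24), list(b))), "mismatch")
  expect_error(average_contrast(list(a, a), n = 25), "at least")
})

test_that("masked pixels stay masked through averaging", {
  f <- matrix(rexp(64) + 1, 8)
  g <- f
  g[1:5, 1:5] <- 0  # force low window means in one corner
  a <- spatial_contrast(f)
  b <- spatial_contrast(g)
  avg <- average_contrast(c(rep(list(a), 24), list(b)), 25)
  expect_true(all(is.na(avg$values[!b$mask])))
})

test_that("flow index is 1/K^2 with zero-contrast pixels masked", {
  m <- spatial_contrast(matrix(rexp(64) + 0.5, 8))
  m$values[] <- 1
  expect_true(all(contrast_to_flow(m)$values == 1))
  m$values[] <- 0.5
  expect_true(all(contrast_to_flow(m)$values == 4))
  m$values[1, 1] <- 0
  expect_warning(fl <- contrast_to_flow(m), "zero contrast")
  expect_identical(fl$n_zero_contrast, 1L)
  expect_true(is.na(fl$values[1, 1]))
})

test_that("Gaussian smoothing preserves constants, mass, and the kernel", {
  const <- structure(
    list(values = matrix(3, 40, 40), mask = matrix(TRUE, 40, 40),
         sigma_smooth_px = NULL, n_zero_contrast = 0L),
    class = "flow_map")
  sm <- smooth_flow(const, 7)
  expect_equal(sm$values, const$values, tolerance = 1e-12)
  expect_equal(sm$sigma_smooth_px, 7)

  set.seed(5)
  rnd <- const
  rnd$values <- matrix(rexp(40 * 40) + 0.1, 40)
  sm <- smooth_flow(rnd, 7)
  expect_equal(sum(sm$values), sum(rnd$values), tolerance = 1e-6)

  # impulse response reproduces the separable kernel (direct evaluation)
  imp <- structure(
    list(values = matrix(0, 61, 61), mask = matrix(TRUE, 61, 61),
         sigma_smooth_px = NULL, n_zero_contrast = 0L),
    class = "flow_map")
  imp$values[31, 31] <- 1
  sigma <- 3
  sm <- smooth_flow(imp, sigma)
  r <- ceiling(4 * sigma)
  k1 <- dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  expect_equal(sm$values[31, 31], max(k1)^2, tolerance = 1e-12)
  expect_equal(sm$values[31, 31 + (-r:r)], k1 * max(k1), tolerance = 1e-12)
})

test_that("ROI statistics use the sample standard deviation", {
  mk <- function(vals) structure(
    list(values = vals, mask = !is.na(vals), sigma_smooth_px = NULL,
         n_zero_contrast = 0L), class = "flow_map")
  m <- mk(matrix(5, 10, 10))
  st <- roi_statistics(m, roi_spec(2, 2, 4, 4))
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 0)
  m <- mk(matrix(c(1, 2, 3, 4), 2, 2))
  st <- roi_statistics(m, roi_spec(1, 1, 2, 2))
  expect_equal(st$mean, 2.5)
  expect_equal(st$sd, sd(1:4))  # 1.2909944...
  expect_error(roi_statistics(m, roi_spec(1, 1, 3, 2)), "beyond")
  m <- mk(matrix(NA_real_, 4, 4))
  expect_error(roi_statistics(m, roi_spec(1, 1, 2, 2)), "unmasked")
})

test_that("the pipeline is deterministic for a fixed movie", {
  cfg <- speckle_config(64, 64, n_frames = 25, tau_c_ms = 2, seed = 77)
  mv <- simulate_speckle_movie(cfg)
  roi <- roi_spec(17, 17, 32, 32)
  a <- lsci_pipeline(mv, roi = roi)
  b <- lsci_pipeline(mv, roi = roi)
  expect_identical(a$mean, b$mean)
  expect_identical(a$flow_map$values, b$flow_map$values)
})
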