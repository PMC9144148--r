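# Speckle generator physics: negative-exponential statistics, the
# finite-exposure contrast curve, and the flow <-> tau_c mapping.

test_that("identical config and seed reproduce the movie bit for bit", {
  cfg <- speckle_config(64, 64, n_frames = 3, tau_c_ms = 5, seed = 9)
  expect_identical(simulate_speckle_movie(cfg)$frames,
                   simulate_speckle_movie(cfg)$frames)
})

test_that("static fully developed speckle has unit global contrast", {
  cfg <- speckle_config(128, 128, n_frames = 20, tau_c_ms = Inf,
                        n_subframes = 1, seed = 4)
  mv <- simulate_speckle_movie(cfg)
  expect_true(all(mv$frames >= 0))
  k <- mean(global_contrast(mv))
  expect_gt(k, 0.9)
  expect_lt(k, 1.1)
})

test_that("the coherence factor scales contrast as sqrt(beta)", {
  cfg <- speckle_config(128, 128, n_frames = 10, tau_c_ms = Inf,
                        n_subframes = 1, beta = 0.25, seed = 5)
  mv <- simulate_speckle_movie(cfg)
  expect_true(all(mv$frames >= 0))
  expect_equal(mean(global_contrast(mv)), 0.5, tolerance = 0.05)
})

test_that("quadrature of the field autocovariance matches the closed form", {
  for (x in c(0.05, 0.1, 0.5, 1, 2, 10, 50)) {
    expect_equal(quad_k2(x), closed_k2(x), tolerance = 1e-8)
  }
})

test_that("time-integrated contrast follows the finite-exposure curve", {
  # one mid-grid point at unit exposure-to-decorrelation ratio; the full
  # {0.1, 1, 10} grid at 256^2 runs in the acceptance suite
  cfg <- speckle_config(128, 128, n_frames = 20, exposure_ms = 10,
                        fps = 30, tau_c_ms = 10, seed = 21)
  mv <- simulate_speckle_movie(cfg)
  expect_equal(measured_k2(mv), quad_k2(1), tolerance = 0.1)
})

test_that("contrast decreases strictly as the field decorrelates faster", {
  k2 <- vapply(c(20, 10, 5), function(tau) {
    cfg <- speckle_config(128, 128, n_frames = 20, tau_c_ms = tau,
                          seed = 31)
    measured_k2(simulate_speckle_movie(cfg))
  }, numeric(1))
  expect_true(all(diff(k2) < 0))
})

test_that("invalid acquisition settings are rejected", {
  expect_error(speckle_config(exposure_ms = 40, fps = 30), "frame period")
  expect_error(speckle_config(beta = 0), "beta")
  expect_error(speckle_config(beta = 1.5), "beta")
  expect_error(speckle_config(tau_c_ms = 0), "tau_c_ms")
  expect_error(speckle_config(speckle_grain_px = 1), "speckle_grain_px")
})

test_that("flow experiment maps relative flow to tau_c inversely", {
  cfg <- speckle_config(64, 64, n_frames = 2, seed = 1)
  ex <- simulate_flow_experiment(0.8, c(baseline = 1, t15min = 0.5), cfg,
                                 seed = 2)
  expect_equal(ex$movies$baseline$provenance$tau_c_ms, 0.8)
  expect_equal(ex$movies$t15min$provenance$tau_c_ms, 1.6)
  expect_equal(unname(ex$true_relative_flow["t15min"]), 0.5)
})

test_that("flow experiments without a unit baseline are rejected", {
  cfg <- speckle_config(64, 64, n_frames = 2)
  expect_error(
    simulate_flow_experiment(1, c(t15min = 0.5), cfg), "baseline")
  expect_error(
    simulate_flow_experiment(1, c(baseline = 0.9, t15min = 0.5), cfg),
    "exactly 1")
  expect_error(
    simulate_flow_experiment(1, c(baseline = 1, t15min = -0.5), cfg),
    "> 0")
})
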