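# Frequency-band splitting, Parseval bookkeeping, alteration, depth
# profiles.

test_that("a pure in-band tone lands entirely in its band", {
  fs <- 4e8
  n <- 8192
  t <- (0:(n - 1)) / fs
  tone <- sqrt(2) * sin(2 * pi * 20e6 * t)  # unit RMS at 20 MHz
  s <- pa_signal(tone, fs)
  b <- band_split_intensity(s)
  tot <- total_power(s)
  expect_equal(b$intensity[b$band == "low"], tot, tolerance = 0.01)
  expect_lt(b$intensity[b$band == "high"], 1e-3 * tot)
})

test_that("the shared 33 MHz edge belongs to the low band only", {
  fs <- 4e8
  n <- 8000  # 33 MHz falls exactly on a DFT bin (fs / n = 50 kHz)
  t <- (0:(n - 1)) / fs
  s <- pa_signal(sin(2 * pi * 33e6 * t), fs)
  b <- band_split_intensity(s)
  expect_equal(b$intensity[b$band == "low"], total_power(s),
               tolerance = 1e-9)
  expect_equal(b$intensity[b$band == "high"], 0, tolerance = 1e-15)
  expect_equal(sum(b$intensity), total_power(s), tolerance = 1e-9)
})

test_that("two-band synthesis obeys Parseval and the injected power ratio", {
  s <- simulate_pa_signal(2, 1, fs = 4e8, duration = 2e-5, seed = 13)
  b <- band_split_intensity(s)
  lo <- b$intensity[b$band == "low"]
  hi <- b$intensity[b$band == "high"]
  expect_equal(lo + hi, total_power(s), tolerance = 0.01)
  expect_equal(lo / hi, 4, tolerance = 0.05)
  # spectral leakage outside [11, 99] MHz, checked by direct integration
  n <- length(s$samples)
  pow <- Mod(fft(s$samples))^2 / n^2
  f_eff <- pmin((0:(n - 1)) * s$fs / n, s$fs - (0:(n - 1)) * s$fs / n)
  outside <- sum(pow[f_eff < 11e6 | f_eff > 99e6])
  expect_lt(outside, 0.01 * sum(pow))
})

test_that("an empty band synthesizes to zero intensity", {
  s <- simulate_pa_signal(1, 0, seed = 2)
  b <- band_split_intensity(s)
  expect_equal(b$intensity[b$band == "high"], 0, tolerance = 1e-12)
})

test_that("band intensities scale quadratically with amplitude", {
  s <- simulate_pa_signal(1.5, 0.7, seed = 5)
  b1 <- band_split_intensity(s)
  s3 <- pa_signal(3 * s$samples, s$fs, s$timepoint_label)
  b3 <- band_split_intensity(s3)
  expect_equal(b3$intensity, 9 * b1$intensity, tolerance = 1e-9)
})

test_that("sub-Nyquist sampling rates are rejected", {
  expect_error(simulate_pa_signal(1, 1, fs = 1e8), "fs")
  wide <- list(band_definition("low", 11e6, 33e6),
               band_definition("high", 33e6, 1.4e8))
  expect_error(simulate_pa_signal(1, 1, fs = 2.6e8, bands = wide),
               "Nyquist")
  s <- pa_signal(rnorm(128), 1.5e8)
  expect_error(band_split_intensity(s), "Nyquist")
  expect_error(band_split_intensity(pa_signal(rnorm(32), 4e8)), "64")
})

test_that("alteration is the percent ratio to the pre-injection value", {
  expect_equal(alteration(5, 5), 100)
  expect_equal(alteration(0, 5), 0)
  expect_equal(alteration(2.5, 5), 50)
  expect_error(alteration(1, 0), "> 0")
  expect_error(alteration(-1, 2), "negative")
})

test_that("the alteration time course is exact on known scalings", {
  tps <- c("before", "5 min", "15 min", "1 h", "24 h", "5 days")
  scal <- c(1, 0.05, 0.1, 0.6, 1.4, 0.8)
  series <- expand.grid(timepoint = tps, band = c("low", "high"),
                        stringsAsFactors = FALSE)
  base <- ifelse(series$band == "low", 8, 2)
  series$intensity <- base * scal[match(series$timepoint, tps)]
  alt <- alteration_timecourse(series, "before")
  expect_equal(alt$alteration_percent,
               100 * scal[match(alt$timepoint, tps)], tolerance = 1e-12)
  expect_true(all(
    alt$alteration_percent[alt$timepoint == "before"] == 100))
})

test_that("bands missing at a timepoint stay absent, not zero", {
  series <- data.frame(
    timepoint = c("before", "before", "24 h"),
    band = c("low", "high", "low"),
    intensity = c(4, 2, 1))
  alt <- alteration_timecourse(series, "before")
  expect_equal(nrow(alt), 3)
  expect_false(any(alt$timepoint == "24 h" & alt$band == "high"))
  expect_error(alteration_timecourse(series, "nope"), "reference")
})

test_that("depth profiles equal per-layer brute-force means", {
  set.seed(8)
  low <- array(rexp(6 * 5 * 4), dim = c(6, 5, 4))
  high <- array(rexp(6 * 5 * 4), dim = c(6, 5, 4))
  vol <- recon_volume(low, high, voxel_mm = 0.25)
  prof <- depth_band_profile(vol)$profile
  for (z in 1:4) {
    expect_equal(prof$low[z], mean(low[, , z]))
    expect_equal(prof$high[z], mean(high[, , z]))
  }
  expect_equal(prof$depth_mm, (0:3) * 0.25)
})

test_that("uniform volumes give flat profiles and no extinction", {
  vol <- recon_volume(array(2, c(4, 4, 5)), array(3, c(4, 4, 5)), 0.1)
  dp <- depth_band_profile(vol)
  expect_true(all(dp$profile$low == 2))
  expect_true(all(dp$profile$high == 3))
  expect_true(is.na(dp$low_band_extinction_mm))
})

test_that("low-band extinction depth is located within one layer", {
  nz <- 20
  spacing <- 0.05
  low <- array(0, c(8, 8, nz))
  low[, , (0:(nz - 1)) * spacing < 0.75] <- 1  # energy confined above 0.75 mm
  high <- array(1, c(8, 8, nz))
  dp <- depth_band_profile(recon_volume(low, high, spacing))
  expect_lte(abs(dp$low_band_extinction_mm - 0.75), spacing)
})

test_that("degenerate volumes are rejected", {
  expect_error(recon_volume(array(1, c(4, 4, 1)), array(1, c(4, 4, 1)), 0.1),
               "2 z layers")
  expect_error(recon_volume(array(1, c(4, 4, 2)), array(1, c(4, 5, 2)), 0.1),
               "identical")
  expect_error(recon_volume(array(1, c(4, 4, 2)), array(1, c(4, 4, 2)), 0),
               "> 0")
})
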