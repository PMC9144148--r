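#' Speckle simulation configuration
#'
#' Bundles the acquisition and ground-truth parameters of a dynamic speckle
#' movie. The defaults mirror the LSCI acquisition used on the exposed
#' kidney surface: 10 ms exposure at 30 frames per second, with a speckle
#' grain of 2 px so the pattern is Nyquist-sampled (the instrument's lens
#' F-stop is tuned for the same criterion).
#'
#' `tau_c_ms` is the decorrelation time of the underlying complex field: the
#' simulator's ground truth for flow. `tau_c_ms = Inf` gives a static
#' (frozen) speckle pattern. `n_subframes` controls the temporal resolution
#' of the finite-exposure integration; when `NULL` it is chosen as
#' `max(8, ceiling(8 * exposure_ms / tau_c_ms))` (capped at 256; 1 for a
#' static field), which keeps the discrete integral within about 2% of the
#' continuous contrast-exposure curve over `exposure/tau_c` up to ~10.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param n_frames Number of stored frames (default 25, matching the 25
#'   contrast frames averaged downstream).
#' @param exposure_ms Camera exposure in ms; must not exceed the frame
#'   period `1000/fps`.
#' @param fps Frame rate in 1/s.
#' @param tau_c_ms Field decorrelation time in ms (> 0, or `Inf` for static
#'   speckle).
#' @param n_subframes Instantaneous speckle fields averaged per exposure
#'   (>= 1), or `NULL` for the automatic rule above.
#' @param beta Coherence factor in (0, 1]: the fraction of detected
#'   intensity variance that is speckle-modulated (polarization/ pixel
#'   integration losses). 1 = ideal fully developed speckle.
#' @param speckle_grain_px Speckle correlation length in pixels (>= 2 so
#'   the field is Nyquist-sampled on the grid).
#' @param seed Optional integer seed.
#' @return A `speckle_config` list.
#' @seealso [simulate_speckle_movie()]
#' @export
speckle_config <- function(frame_height = 256, frame_width = 256,
                           n_frames = 25, exposure_ms = 10, fps = 30,
                           tau_c_ms = 1, n_subframes = NULL, beta = 1,
                           speckle_grain_px = 2, seed = NULL) {
  frame_height <- check_count(frame_height, "frame_height", lower = 16L)
  frame_width <- check_count(frame_width, "frame_width", lower = 16L)
  n_frames <- check_count(n_frames, "n_frames")
  check_scalar_num(exposure_ms, "exposure_ms", lower = 0, strict_lower = TRUE)
  check_scalar_num(fps, "fps", lower = 0, strict_lower = TRUE)
  if (exposure_ms > 1000 / fps + 1e-9) {
    stop("exposure_ms (", exposure_ms, ") exceeds the frame period ",
         signif(1000 / fps, 6), " ms at fps = ", fps, call. = FALSE)
  }
  check_scalar_num(tau_c_ms, "tau_c_ms", lower = 0, strict_lower = TRUE,
                   allow_inf = TRUE)
  check_scalar_num(beta, "beta", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar_num(speckle_grain_px, "speckle_grain_px", lower = 2)
  static <- is.infinite(tau_c_ms)
  if (is.null(n_subframes)) {
    n_subframes <- if (static) 1L else
      as.integer(max(8, min(256, ceiling(8 * exposure_ms / tau_c_ms))))
  } else {
    n_subframes <- check_count(n_subframes, "n_subframes")
  }
  structure(
    list(frame_height = frame_height, frame_width = frame_width,
         n_frames = n_frames, exposure_ms = exposure_ms, fps = fps,
         tau_c_ms = tau_c_ms, n_subframes = n_subframes, beta = beta,
         speckle_grain_px = speckle_grain_px, seed = seed),
    class = "speckle_config"
  )
}

# circular pupil support in the 2-D FFT index plane. The field
# autocorrelation is the Airy pattern of the pupil; its first zero — the
# conventional "speckle size" — sits at 0.61 * N / r px, so the radius is
# chosen to put that zero at `grain` pixels.
pupil_mask <- function(h, w, grain) {
  r <- 0.61 * min(h, w) / grain
  ky <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[seq_len(h)]
  kx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[seq_len(w)]
  outer(ky^2, kx^2, "+") <= r^2
}

# one instantaneous fully developed speckle intensity field from pupil-plane
# coefficients `a` (complex, unit variance); mean intensity normalized to 1
speckle_intensity <- function(a, mask, m) {
  A <- matrix(0 + 0i, nrow(mask), ncol(mask))
  A[mask] <- a
  f <- stats::fft(A, inverse = TRUE)
  (Re(f)^2 + Im(f)^2) / m
}

complex_gaussian <- function(m) {
  complex(real = stats::rnorm(m, sd = sqrt(0.5)),
          imaginary = stats::rnorm(m, sd = sqrt(0.5)))
}

#' Simulate a dynamic speckle movie
#'
#' Generates a stack of time-integrated speckle frames from a complex
#' circular-Gaussian field defined by random pupil-plane coefficients
#' (uniform circular pupil, so the field is Fourier-limited with the
#' requested grain size). The field evolves as a first-order autoregressive
#' process with coefficient `exp(-dt / tau_c)`, which gives an exponential
#' field autocorrelation `g1(t) = exp(-t / tau_c)`. Each stored frame is the
#' mean of `n_subframes` instantaneous intensities spread over the exposure;
#' the field keeps evolving through the dead time between exposures.
#'
#' Instantaneous single-field intensities follow negative-exponential
#' statistics (spatial contrast 1), and the time-integrated spatial contrast
#' follows the classic finite-exposure curve
#' \deqn{K^2 = \beta \, \frac{e^{-2x} - 1 + 2x}{2x^2}, \quad x = T/\tau_c,}
#' which the test-suite checks against numerical quadrature of the field
#' autocovariance.
#'
#' @param cfg A [speckle_config()].
#' @return A `speckle_movie`: list with `frames` (array
#'   `n_frames x height x width`, non-negative, mean ~1), `exposure_ms`,
#'   `fps`, and `provenance` (the config).
#' @examples
#' cfg <- speckle_config(frame_height = 64, frame_width = 64, n_frames = 2,
#'                       tau_c_ms = Inf, seed = 1)
#' mv <- simulate_speckle_movie(cfg)
#' global_contrast(mv)  # ~1 for static fully developed speckle
#' @export
simulate_speckle_movie <- function(cfg) {
  stopifnot(inherits(cfg, "speckle_config"))
  h <- cfg$frame_height; w <- cfg$frame_width
  mask <- pupil_mask(h, w, cfg$speckle_grain_px)
  m <- sum(mask)
  static <- is.infinite(cfg$tau_c_ms)
  n_sub <- cfg$n_subframes
  dt_sub <- cfg$exposure_ms / n_sub
  gap_ms <- 1000 / cfg$fps - cfg$exposure_ms
  rho_sub <- if (static) 1 else exp(-dt_sub / cfg$tau_c_ms)
  rho_gap <- if (static) 1 else exp(-max(gap_ms, 0) / cfg$tau_c_ms)
  frames <- with_seed_(cfg$seed, {
    a <- complex_gaussian(m)
    out <- array(0, dim = c(cfg$n_frames, h, w))
    mix_sub <- sqrt(1 - rho_sub^2)
    mix_gap <- sqrt(1 - rho_gap^2)
    for (fr in seq_len(cfg$n_frames)) {
      acc <- matrix(0, h, w)
      for (s in seq_len(n_sub)) {
        acc <- acc + speckle_intensity(a, mask, m)
        if (!static) a <- rho_sub * a + mix_sub * complex_gaussian(m)
      }
      frame <- acc / n_sub
      if (cfg$beta < 1) {
        frame <- sqrt(cfg$beta) * (frame - 1) + 1
      }
      out[fr, , ] <- frame
      if (!static && gap_ms > 0) a <- rho_gap * a + mix_gap * complex_gaussian(m)
    }
    out
  })
  structure(
    list(frames = frames, exposure_ms = cfg$exposure_ms, fps = cfg$fps,
         provenance = cfg),
    class = "speckle_movie"
  )
}

#' @export
print.speckle_movie <- function(x, ...) {
  d <- dim(x$frames)
  tau <- if (inherits(x$provenance, "speckle_config"))
    x$provenance$tau_c_ms else NA
  cat(sprintf(
    "<speckle_movie> %d frames of %d x %d px, T = %g ms @ %g fps, tau_c = %s ms\n",
    d[1], d[2], d[3], x$exposure_ms, x$fps, format(tau)
  ))
  invisible(x)
}

#' Global spatial contrast of each frame
#'
#' `sd(frame) / mean(frame)` over all pixels, per frame — the whole-frame
#' counterpart of the sliding-window contrast, useful for checking speckle
#' statistics (a fully developed static pattern has contrast 1).
#'
#' @param movie A `speckle_movie` or a 3-D array (frame, row, col).
#' @return Numeric vector of per-frame contrasts.
#' @export
global_contrast <- function(movie) {
  frames <- if (inherits(movie, "speckle_movie")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3)
  apply(frames, 1, function(f) stats::sd(f) / mean(f))
}

#' Simulate a multi-timepoint flow experiment with known ground truth
#'
#' Produces one speckle movie per timepoint with the field decorrelation
#' time mapped from the true relative flow as
#' `tau_c = baseline_tau_c / relative_flow` — the standard single-scattering
#' LSCI assumption that flow is inversely proportional to decorrelation
#' time. The baseline timepoint (relative flow 1) plays the role of the
#' pre-injection measurement that all later values are normalized to.
#'
#' @param baseline_tau_c_ms Decorrelation time at baseline, ms (> 0).
#' @param relative_flows Named numeric vector/list of true flow as a
#'   fraction of baseline, one entry per timepoint; must contain
#'   `baseline_label` with value 1, and all fractions must be > 0.
#' @param cfg A [speckle_config()] shared by all timepoints (its `tau_c_ms`
#'   and `seed` are overridden per timepoint).
#' @param baseline_label Name of the baseline entry (default `"baseline"`).
#' @param seed Optional integer seed; per-timepoint movie seeds are derived
#'   from it so each timepoint gets an independent realization.
#' @return A `flow_experiment`: list with `movies` (named list of
#'   `speckle_movie`), `true_relative_flow`, `baseline_label`.
#' @seealso [lsci_pipeline()], [normalize_to_baseline()]
#' @export
simulate_flow_experiment <- function(baseline_tau_c_ms, relative_flows, cfg,
                                     baseline_label = "baseline",
                                     seed = NULL) {
  check_scalar_num(baseline_tau_c_ms, "baseline_tau_c_ms", lower = 0,
                   strict_lower = TRUE)
  stopifnot(inherits(cfg, "speckle_config"))
  rf <- unlist(relative_flows)
  if (is.null(names(rf)) || any(names(rf) == "")) {
    stop("`relative_flows` must be a named vector of timepoint fractions",
         call. = FALSE)
  }
  if (!baseline_label %in% names(rf)) {
    stop("`relative_flows` is missing the baseline label \"",
         baseline_label, "\"", call. = FALSE)
  }
  if (abs(rf[[baseline_label]] - 1) > 1e-12) {
    stop("relative flow at the baseline label must be exactly 1",
         call. = FALSE)
  }
  if (any(rf <= 0)) stop("all relative flows must be > 0", call. = FALSE)
  base_seed <- seed %||% cfg$seed
  movies <- vector("list", length(rf))
  names(movies) <- names(rf)
  for (i in seq_along(rf)) {
    cfg_i <- cfg
    cfg_i$tau_c_ms <- baseline_tau_c_ms / rf[[i]]
    # re-resolve the subframe rule for the new tau_c
    cfg_i <- speckle_config(
      frame_height = cfg$frame_height, frame_width = cfg$frame_width,
      n_frames = cfg$n_frames, exposure_ms = cfg$exposure_ms, fps = cfg$fps,
      tau_c_ms = cfg_i$tau_c_ms, n_subframes = NULL, beta = cfg$beta,
      speckle_grain_px = cfg$speckle_grain_px,
      seed = if (is.null(base_seed)) NULL else base_seed + i - 1L
    )
    movies[[i]] <- simulate_speckle_movie(cfg_i)
  }
  structure(
    list(movies = movies, true_relative_flow = rf,
         baseline_label = baseline_label),
    class = "flow_experiment"
  )
}
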