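#' Construct an optoacoustic signal object
#'
#' A broadband acoustic trace with its sampling rate, as captured by the
#' mesoscope transducer for one timepoint.
#'
#' @param samples Numeric vector of acoustic amplitudes (finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param timepoint_label Timepoint label, e.g. `"before"` or `"15 min"`.
#' @return A `pa_signal` object.
#' @export
pa_signal <- function(samples, fs, timepoint_label = "signal") {
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("`samples` must be finite numeric", call. = FALSE)
  }
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  structure(list(samples = as.numeric(samples), fs = fs,
                 timepoint_label = timepoint_label),
            class = "pa_signal")
}

#' @export
print.pa_signal <- function(x, ...) {
  cat(sprintf("<pa_signal> \"%s\": %d samples @ %.3g MHz, RMS %.4g\n",
              x$timepoint_label, length(x$samples), x$fs / 1e6,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

# two-sided spectral band mask on the fft frequency grid; shared interior
# edges go to the lower band (handled by the caller via strict lower edge)
band_mask <- function(n, fs, f_lo, f_hi, include_lower_edge = TRUE) {
  freq <- (seq_len(n) - 1) * fs / n
  f_eff <- pmin(freq, fs - freq)
  if (include_lower_edge) {
    f_eff >= f_lo & f_eff <= f_hi
  } else {
    f_eff > f_lo & f_eff <= f_hi
  }
}

#' Simulate a two-band optoacoustic signal
#'
#' Sum of two independent band-limited Gaussian noise processes with exact
#' RMS amplitudes, confined by spectral masking to the low (11-33 MHz) and
#' high (33-99 MHz) transducer bands. Because the confinement is a
#' brick-wall mask, spectral leakage outside the bands is identically zero
#' and Parseval bookkeeping is exact, which makes the generator a tight
#' oracle for [band_split_intensity()].
#'
#' @param amp_low,amp_high RMS amplitude of the low/high band component
#'   (>= 0; power in a band is the squared RMS).
#' @param fs Sampling rate in Hz; must be at least 250 MHz so the 99 MHz
#'   band edge is comfortably below Nyquist.
#' @param duration Signal duration in seconds (default 20 microseconds).
#' @param bands A list of two [band_definition()]s (default
#'   [default_pa_bands()]).
#' @param timepoint_label Label stored on the signal.
#' @param seed Optional integer seed.
#' @return A [pa_signal()].
#' @export
simulate_pa_signal <- function(amp_low, amp_high, fs = 4e8,
                               duration = 2e-5, bands = default_pa_bands(),
                               timepoint_label = "signal", seed = NULL) {
  check_scalar_num(amp_low, "amp_low", lower = 0)
  check_scalar_num(amp_high, "amp_high", lower = 0)
  check_scalar_num(fs, "fs", lower = 2.5e8)
  check_scalar_num(duration, "duration", lower = 0, strict_lower = TRUE)
  stopifnot(length(bands) == 2)
  f_hi_max <- max(vapply(bands, function(b) b$f_hi, numeric(1)))
  if (fs <= 2 * f_hi_max) {
    stop("fs = ", fs, " Hz is below Nyquist for the ", f_hi_max / 1e6,
         " MHz band edge", call. = FALSE)
  }
  n <- max(64L, as.integer(round(fs * duration)))
  amps <- c(amp_low, amp_high)
  x <- with_seed_(seed, {
    out <- numeric(n)
    for (i in 1:2) {
      if (amps[i] == 0) next
      mask <- band_mask(n, fs, bands[[i]]$f_lo, bands[[i]]$f_hi,
                        include_lower_edge = i == 1)
      comp <- Re(stats::fft(stats::fft(stats::rnorm(n)) * mask,
                            inverse = TRUE)) / n
      out <- out + comp * amps[i] / sqrt(mean(comp^2))
    }
    out
  })
  pa_signal(x, fs, timepoint_label)
}
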