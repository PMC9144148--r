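#' Define a frequency band
#'
#' @param name Band label, e.g. `"low"`.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  check_scalar_num(f_lo, "f_lo", lower = 0, strict_lower = TRUE)
  check_scalar_num(f_hi, "f_hi", lower = f_lo, strict_lower = TRUE)
  structure(list(name = as.character(name), f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' The standard transducer bands
#'
#' The two analysis bands of the 11-99 MHz mesoscopy transducer:
#' low frequency 11-33 MHz (large vessels) and high frequency 33-99 MHz
#' (small vessels and capillaries).
#'
#' @return List of two [band_definition()]s named `low` and `high`.
#' @export
default_pa_bands <- function() {
  list(low = band_definition("low", 11e6, 33e6),
       high = band_definition("high", 33e6, 99e6))
}

#' Per-band mean power of an acoustic signal
#'
#' Splits a broadband trace into frequency bands by ideal (brick-wall)
#' spectral masking and reports each band's intensity, defined as the mean
#' power (mean squared amplitude) of the band-limited component. By
#' Parseval's theorem the band intensities of a signal fully contained in
#' the union of the bands sum to its total mean power. A frequency bin
#' falling exactly on an edge shared by two bands is assigned to the lower
#' band, so interior energy is never double-counted.
#'
#' @param signal A [pa_signal()] with at least 64 samples; `fs` must exceed
#'   twice the highest band edge.
#' @param bands List of [band_definition()]s (default [default_pa_bands()]).
#' @return A data frame with columns `timepoint`, `band`, `intensity`.
#' @examples
#' s <- simulate_pa_signal(2, 1, seed = 1)
#' band_split_intensity(s)
#' @export
band_split_intensity <- function(signal, bands = default_pa_bands()) {
  stopifnot(inherits(signal, "pa_signal"))
  if (length(signal$samples) < 64) {
    stop("signal must have at least 64 samples", call. = FALSE)
  }
  edges <- vapply(bands, function(b) b$f_hi, numeric(1))
  if (any(2 * edges >= signal$fs)) {
    stop("band edge ", max(edges) / 1e6, " MHz is at or above Nyquist (fs = ",
         signal$fs / 1e6, " MHz)", call. = FALSE)
  }
  n <- length(signal$samples)
  X <- stats::fft(signal$samples)
  pow <- Mod(X)^2 / n^2
  freq <- (seq_len(n) - 1) * signal$fs / n
  f_eff <- pmin(freq, signal$fs - freq)
  assigned <- rep(FALSE, n)
  ord <- order(vapply(bands, function(b) b$f_lo, numeric(1)))
  out <- data.frame(
    timepoint = signal$timepoint_label,
    band = vapply(bands, function(b) b$name, character(1)),
    intensity = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in ord) {
    b <- bands[[i]]
    sel <- !assigned & f_eff >= b$f_lo & f_eff <= b$f_hi
    assigned <- assigned | sel
    out$intensity[i] <- sum(pow[sel])
  }
  out
}

#' Total mean power of a signal
#'
#' `mean(samples^2)`, the Parseval counterpart of the summed band
#' intensities.
#'
#' @param signal A [pa_signal()] or numeric vector.
#' @return Scalar mean power.
#' @export
total_power <- function(signal) {
  x <- if (inherits(signal, "pa_signal")) signal$samples else signal
  mean(x^2)
}

#' Acoustic-signal alteration
#'
#' The alteration `A = 100 * I_t / I_0` of a band intensity relative to
#' its pre-injection value: 100% means unchanged, 0% means the band has
#' vanished (e.g. fully arrested perfusion).
#'
#' @param intensity_t Band intensity at the timepoint (>= 0).
#' @param intensity_0 Band intensity before injection (> 0).
#' @return Alteration in percent.
#' @export
alteration <- function(intensity_t, intensity_0) {
  if (any(!is.finite(intensity_0)) || any(intensity_0 <= 0)) {
    stop("pre-injection intensity must be > 0; the alteration is ",
         "undefined for an absent reference band", call. = FALSE)
  }
  if (any(intensity_t < 0)) {
    stop("band intensities cannot be negative", call. = FALSE)
  }
  100 * intensity_t / intensity_0
}

#' Alteration time course per band
#'
#' Expresses every band intensity as a percentage of the same band's value
#' at the reference (pre-injection) timepoint. The reference maps to
#' exactly 100% in every band. A band missing at some timepoint is simply
#' absent from the output (never reported as zero).
#'
#' @param series Data frame with columns `timepoint`, `band`, `intensity`
#'   (e.g. rbind-ed outputs of [band_split_intensity()]).
#' @param reference_label Timepoint label of the pre-injection reference;
#'   must be present for every band in the series.
#' @return Data frame `timepoint`, `band`, `alteration_percent`.
#' @export
alteration_timecourse <- function(series, reference_label = "before") {
  stopifnot(is.data.frame(series),
            all(c("timepoint", "band", "intensity") %in% names(series)))
  out <- series
  out$alteration_percent <- NA_real_
  for (b in unique(series$band)) {
    sel <- series$band == b
    ref <- series$intensity[sel & series$timepoint == reference_label]
    if (length(ref) != 1) {
      stop("band \"", b, "\" has ", length(ref), " entries at the ",
           "reference timepoint \"", reference_label, "\" (need exactly 1)",
           call. = FALSE)
    }
    out$alteration_percent[sel] <- alteration(series$intensity[sel], ref)
  }
  out[, c("timepoint", "band", "alteration_percent")]
}

#' Construct a two-band reconstructed volume
#'
#' Co-registered low-band and high-band intensity volumes from a
#' reconstructed mesoscopy scan, stored as 3-D arrays indexed
#' `[row, col, z]` with the z axis running from the organ surface inward.
#'
#' @param low,high Non-negative 3-D arrays of equal dimension, >= 2 z
#'   layers.
#' @param voxel_mm Voxel spacing in mm (length 1 or 3, > 0).
#' @return A `recon_volume` list.
#' @export
recon_volume <- function(low, high, voxel_mm) {
  if (!is.array(low) || !is.array(high) || length(dim(low)) != 3 ||
      !identical(dim(low), dim(high))) {
    stop("`low` and `high` must be 3-D arrays of identical dimension",
         call. = FALSE)
  }
  if (dim(low)[3] < 2) {
    stop("volume needs at least 2 z layers", call. = FALSE)
  }
  voxel_mm <- rep(voxel_mm, length.out = 3)
  if (any(voxel_mm <= 0)) stop("voxel spacing must be > 0", call. = FALSE)
  structure(list(low = low, high = high, voxel_mm = voxel_mm),
            class = "recon_volume")
}

#' Depth-resolved band intensity profile
#'
#' Mean intensity of each band per z layer of a reconstructed volume
#' (splitting the 3-D reconstruction into separate layers), plus the
#' low-band extinction depth: the depth of the first layer, moving inward
#' from the surface, at which the low-band layer mean has fallen to at
#' most `surface_fraction` of its surface value. Large vessels, carrying
#' the low-frequency signal, are typically not visualized beyond ~0.75 mm.
#'
#' @param volume A [recon_volume()].
#' @param surface_fraction Extinction threshold as a fraction of the
#'   surface-layer mean (default 0.05).
#' @return List with `profile` (data frame `depth_mm`, `low`, `high`;
#'   depth 0 at the surface layer) and `low_band_extinction_mm` (`NA` if
#'   the low band persists through the whole volume).
#' @export
depth_band_profile <- function(volume, surface_fraction = 0.05) {
  stopifnot(inherits(volume, "recon_volume"))
  check_scalar_num(surface_fraction, "surface_fraction", lower = 0,
                   upper = 1)
  nz <- dim(volume$low)[3]
  depth <- (seq_len(nz) - 1) * volume$voxel_mm[3]
  low <- vapply(seq_len(nz), function(z) mean(volume$low[, , z]), numeric(1))
  high <- vapply(seq_len(nz), function(z) mean(volume$high[, , z]), numeric(1))
  ext <- NA_real_
  if (low[1] > 0) {
    gone <- which(low <= surface_fraction * low[1])
    if (length(gone)) ext <- depth[min(gone)]
  }
  list(profile = data.frame(depth_mm = depth, low = low, high = high),
       low_band_extinction_mm = ext)
}
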