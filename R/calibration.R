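#' Fit a dye-mass calibration line
#'
#' Ordinary least-squares fit of `intensity = intercept + slope * mass` to
#' calibration standards — kidney digests spiked with known dye-conjugate
#' masses, read at the 785 nm emission peak. A valid curve has a strictly
#' positive slope.
#'
#' @param mass Known standard masses (>= 3 values, >= 2 distinct).
#' @param intensity Measured emission intensities at 785 nm, same length.
#' @return A `calibration_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `wavelength_nm` (785) and `n_standards`.
#' @examples
#' fit_calibration(c(0, 1, 2), c(1, 3, 5))  # slope 2, intercept 1
#' @export
fit_calibration <- function(mass, intensity) {
  if (length(mass) < 3 || length(intensity) != length(mass)) {
    stop("need >= 3 (mass, intensity) standard pairs", call. = FALSE)
  }
  if (length(unique(mass)) < 2) {
    stop("all standard masses are identical: the slope is unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(intensity ~ mass)
  cf <- stats::coef(fit)
  slope <- unname(cf["mass"])
  if (!is.finite(slope) || slope <= 0) {
    stop("fitted slope is not positive (", signif(slope, 4),
         "): calibration standards do not show a dye response",
         call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  structure(
    list(slope = slope, intercept = unname(cf["(Intercept)"]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         wavelength_nm = 785, n_standards = length(mass)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> I(785 nm) = %.4g + %.4g * mass  (r^2 = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n_standards
  ))
  invisible(x)
}

# intensity at 785 nm from a spectrum matrix/vector on a wavelength grid
intensity_at_785 <- function(wavelengths, intensities) {
  i <- which(wavelengths == 785)
  if (length(i) != 1) {
    stop("785 nm is not on the wavelength grid; the calibration ",
         "wavelength must be present", call. = FALSE)
  }
  if (is.matrix(intensities)) intensities[i, ] else intensities[i]
}

#' Dye mass from emission spectra via a calibration curve
#'
#' Inverts the calibration line at the 785 nm emission peak:
#' `mass = (I_785 - intercept) / slope`. When several replicate wells of
#' the same sample are supplied (columns of a matrix), their 785 nm
#' intensities are averaged *before* inversion — the replicate-handling
#' convention used throughout the package. A negative inverted mass is
#' clamped to zero and flagged.
#'
#' @param wavelengths Wavelength grid in nm; must contain 785.
#' @param intensities Emission spectrum (vector) or replicate spectra
#'   (matrix with one column per well), one intensity per wavelength.
#' @param curve A [fit_calibration()] result.
#' @return Estimated mass (scalar) with attribute `clamped` (logical).
#' @export
mass_from_spectrum <- function(wavelengths, intensities, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  nwl <- if (is.matrix(intensities)) nrow(intensities) else
    length(intensities)
  if (nwl != length(wavelengths)) {
    stop("`intensities` must have one value per wavelength", call. = FALSE)
  }
  i785 <- mean(intensity_at_785(wavelengths, intensities))
  mass <- (i785 - curve$intercept) / curve$slope
  # round-off guard: an intensity numerically at the intercept is mass 0,
  # not a flagged negative
  tol <- 1e-9 * max(1, abs(i785), abs(curve$intercept)) / curve$slope
  if (mass < 0 && mass >= -tol) mass <- 0
  clamped <- mass < 0
  if (clamped) {
    warning("inverted mass was negative (", signif(mass, 4),
            "); clamped to 0")
    mass <- 0
  }
  structure(mass, clamped = clamped)
}

#' Calibrate and quantify a whole fluorimetry plate
#'
#' Fits the calibration line from the plate's standard wells and inverts it
#' for every sample (averaging each sample's replicate wells at 785 nm
#' first).
#'
#' @param plate A [simulate_fluorimetry_plate()] result (or compatible
#'   list with `wavelengths`, `wells`, `standards`, `sample_wells`).
#' @param curve Optional pre-fitted [fit_calibration()] curve; by default
#'   the plate's own standards are used.
#' @return List with `curve` and `masses`: data frame `sample`,
#'   `mass_est`, `clamped`, and `mass_true` when the plate carries ground
#'   truth.
#' @export
quantify_plate <- function(plate, curve = NULL) {
  stopifnot(is.list(plate),
            all(c("wavelengths", "wells", "standards", "sample_wells")
                %in% names(plate)))
  if (is.null(curve)) {
    std_i <- intensity_at_785(plate$wavelengths,
                              plate$wells[, names(plate$standards),
                                          drop = FALSE])
    curve <- fit_calibration(unname(plate$standards), unname(std_i))
  }
  res <- lapply(names(plate$sample_wells), function(id) {
    wells <- plate$wells[, plate$sample_wells[[id]], drop = FALSE]
    m <- mass_from_spectrum(plate$wavelengths, wells, curve)
    data.frame(sample = id, mass_est = as.numeric(m),
               clamped = attr(m, "clamped"), stringsAsFactors = FALSE)
  })
  masses <- do.call(rbind, res)
  if (!is.null(plate$truth)) {
    masses$mass_true <- unname(plate$truth[masses$sample])
  }
  list(curve = curve, masses = masses)
}
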