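#' Simulate a fluorimetry calibration/quantification plate
#'
#' Emulates the plate-reader step of the enzymatic-digest dye assay:
#' emission spectra on a 770-840 nm grid (1 nm step, 745 nm excitation)
#' with a smooth emission peak near 785 nm whose height responds linearly
#' to dye-conjugate mass, `intensity_785 = intercept + slope * mass`, plus
#' additive Gaussian read noise. Standards (kidney digests spiked with
#' known dye amounts) occupy one well each; every unknown sample is
#' dispensed into 5 replicate wells, mirroring the bench protocol.
#'
#' @param standard_masses Numeric vector of >= 3 known standard masses
#'   (>= 2 distinct values).
#' @param sample_masses Numeric vector of true (ground-truth) sample masses.
#' @param slope Emission intensity per unit mass at 785 nm (> 0).
#' @param intercept Baseline emission intensity at 785 nm (>= 0), the
#'   digest's own background.
#' @param noise_sd Additive Gaussian noise SD on each spectrum (>= 0).
#' @param n_replicates Wells per unknown sample (default 5).
#' @param seed Optional integer seed.
#' @return A `fluorimetry_plate`: list with `wavelengths` (770:840),
#'   `wells` (matrix, one column per well), `standards` (named mass vector
#'   for the standard wells), `sample_wells` (named list: sample id ->
#'   replicate well ids) and `truth` (named true masses).
#' @seealso [fit_calibration()], [mass_from_spectrum()], [quantify_plate()]
#' @export
simulate_fluorimetry_plate <- function(standard_masses, sample_masses,
                                       slope, intercept = 0, noise_sd = 0,
                                       n_replicates = 5, seed = NULL) {
  if (length(standard_masses) < 3) {
    stop("need at least 3 calibration standards", call. = FALSE)
  }
  if (length(unique(standard_masses)) < 2) {
    stop("standards must contain at least 2 distinct masses", call. = FALSE)
  }
  if (any(standard_masses < 0) || any(sample_masses < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  check_scalar_num(slope, "slope", lower = 0, strict_lower = TRUE)
  check_scalar_num(intercept, "intercept", lower = 0)
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates")

  wl <- 770:840
  # emission lineshape peaking at 785 nm, unit height at the peak; width
  # typical of a heptamethine cyanine emission band
  shape <- exp(-(wl - 785)^2 / (2 * 18^2))

  std_ids <- sprintf("std%02d", seq_along(standard_masses))
  sample_ids <- sprintf("smp%02d", seq_along(sample_masses))
  sample_wells <- lapply(sample_ids, function(id) {
    paste0(id, "_r", seq_len(n_replicates))
  })
  names(sample_wells) <- sample_ids
  well_ids <- c(std_ids, unlist(sample_wells))
  well_mass <- c(standard_masses, rep(sample_masses, each = n_replicates))

  wells <- with_seed_(seed, {
    peak <- intercept + slope * well_mass
    m <- outer(shape, peak)
    if (noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m))
    }
    m
  })
  dimnames(wells) <- list(NULL, well_ids)
  truth <- stats::setNames(sample_masses, sample_ids)
  structure(
    list(wavelengths = wl, wells = wells,
         standards = stats::setNames(standard_masses, std_ids),
         sample_wells = sample_wells, truth = truth),
    class = "fluorimetry_plate"
  )
}

#' @export
print.fluorimetry_plate <- function(x, ...) {
  cat(sprintf(
    "<fluorimetry_plate> %d-%d nm, %d wells (%d standards, %d samples x %d replicates)\n",
    min(x$wavelengths), max(x$wavelengths), ncol(x$wells),
    length(x$standards), length(x$sample_wells),
    length(x$sample_wells[[1]] %||% integer(0))
  ))
  invisible(x)
}
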