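#' The dissected-organ panel
#'
#' The nine organs imaged ex vivo in the biodistribution assay: both
#' kidneys, lungs, heart, liver, spleen, stomach, intestines, appendix.
#'
#' @return Character vector of organ names.
#' @export
renal_organs <- function() {
  c("left kidney", "right kidney", "lungs", "heart", "liver", "spleen",
    "stomach", "intestines", "appendix")
}

#' Plausible organ image areas
#'
#' Default per-organ image areas (arbitrary units, roughly proportional to
#' the projected area of each mouse organ in an ex vivo IVIS image) for the
#' organ-table generator.
#'
#' @return Named numeric vector over [renal_organs()].
#' @export
default_organ_areas <- function() {
  c("left kidney" = 1.2, "right kidney" = 1.2, "lungs" = 1.5,
    "heart" = 1.0, "liver" = 4.0, "spleen" = 0.8, "stomach" = 2.0,
    "intestines" = 5.0, "appendix" = 0.6)
}

# multiplicative log-normal factor with unit mean and coefficient of
# variation cv (fluorescence intensities are positive and right-skewed)
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Simulate experimental and control organ fluorescence tables
#'
#' Emulates the ex vivo organ imaging readout: each organ's total radiant
#' efficiency (TRE) is an autofluorescence term proportional to the organ's
#' image area plus — in the experimental animal — a dye-signal term
#' proportional to the organ's true share of the injected dose. The control
#' animal (no injection) carries autofluorescence only. Noise is
#' multiplicative log-normal with the given coefficient of variation,
#' applied independently to the dye and autofluorescence components.
#'
#' @param true_percent_id Named numeric over organs, the true %ID; must be
#'   non-negative and sum to 100.
#' @param autofl_per_area Autofluorescence TRE per unit area (>= 0).
#' @param areas Named numeric of organ image areas (> 0); defaults to
#'   [default_organ_areas()] restricted to the organs of `true_percent_id`.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param signal_total Total dye TRE for a full dose (same units as
#'   `autofl_per_area * area`); default 5x the summed autofluorescence, a
#'   realistic ex vivo signal-to-background for a near-infrared dye.
#' @param seed Optional integer seed.
#' @return List with `experimental` and `control` data frames (columns
#'   `organ`, `tre`, `area`, `group`) and `truth` (the input %ID vector).
#' @seealso [correct_autofluorescence()], [percent_id_from_tre()]
#' @export
simulate_organ_tables <- function(true_percent_id, autofl_per_area,
                                  areas = NULL, noise_cv = 0.05,
                                  signal_total = NULL, seed = NULL) {
  tid <- unlist(true_percent_id)
  if (is.null(names(tid)) || any(names(tid) == "")) {
    stop("`true_percent_id` must be named by organ", call. = FALSE)
  }
  if (anyDuplicated(names(tid))) {
    stop("organ names must be unique", call. = FALSE)
  }
  if (any(tid < 0)) {
    stop("`true_percent_id` entries must be non-negative", call. = FALSE)
  }
  if (abs(sum(tid) - 100) > 1e-9) {
    stop("`true_percent_id` must sum to 100 (got ", sum(tid), ")",
         call. = FALSE)
  }
  check_scalar_num(autofl_per_area, "autofl_per_area", lower = 0)
  check_scalar_num(noise_cv, "noise_cv", lower = 0)
  if (is.null(areas)) {
    defaults <- default_organ_areas()
    missing <- setdiff(names(tid), names(defaults))
    if (length(missing)) {
      stop("no default area for organ(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    areas <- defaults[names(tid)]
  } else {
    areas <- unlist(areas)[names(tid)]
    if (anyNA(areas)) stop("`areas` must cover every organ", call. = FALSE)
  }
  if (any(areas <= 0)) stop("all areas must be > 0", call. = FALSE)
  autofl <- autofl_per_area * areas
  signal_total <- signal_total %||% (5 * sum(autofl))
  check_scalar_num(signal_total, "signal_total", lower = 0)
  n <- length(tid)
  with_seed_(seed, {
    signal <- signal_total * tid / 100 * lognormal_factor(n, noise_cv)
    tre_exp <- signal + autofl * lognormal_factor(n, noise_cv)
    tre_ctrl <- autofl * lognormal_factor(n, noise_cv)
    list(
      experimental = data.frame(
        organ = names(tid), tre = unname(tre_exp), area = unname(areas),
        group = "experimental", stringsAsFactors = FALSE
      ),
      control = data.frame(
        organ = names(tid), tre = unname(tre_ctrl), area = unname(areas),
        group = "control", stringsAsFactors = FALSE
      ),
      truth = tid
    )
  })
}
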