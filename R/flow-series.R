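#' Normalize ROI flow values to an individual baseline
#'
#' Expresses each timepoint's ROI-mean flow index as a percentage of the
#' same subject's pre-injection (baseline) value:
#' `percent = 100 * mean[t] / mean[baseline]`. Normalizing within the
#' individual removes inter-animal differences in absolute flow index.
#'
#' @param means Named numeric vector of ROI-mean flow indices in timepoint
#'   order; names are the timepoint labels.
#' @param baseline_label Label of the baseline entry (must be present with
#'   a strictly positive value).
#' @param sds Optional named numeric of ROI standard deviations.
#' @return A `flow_series` data frame with columns `timepoint`, `roi_mean`,
#'   `roi_sd`, `percent_of_baseline`; the baseline row is exactly 100.
#' @examples
#' normalize_to_baseline(c(baseline = 2, `15 min` = 1), "baseline")
#' @export
normalize_to_baseline <- function(means, baseline_label = "baseline",
                                  sds = NULL) {
  means <- unlist(means)
  if (is.null(names(means)) || any(names(means) == "")) {
    stop("`means` must be named by timepoint", call. = FALSE)
  }
  if (anyDuplicated(names(means))) {
    stop("timepoint labels must be unique", call. = FALSE)
  }
  if (!baseline_label %in% names(means)) {
    stop("baseline label \"", baseline_label, "\" not found", call. = FALSE)
  }
  base <- means[[baseline_label]]
  if (!is.finite(base) || base <= 0) {
    stop("baseline flow must be a positive number (got ", base, ")",
         call. = FALSE)
  }
  sds <- if (is.null(sds)) rep(NA_real_, length(means)) else
    unlist(sds)[names(means)]
  out <- data.frame(
    timepoint = names(means),
    roi_mean = unname(means),
    roi_sd = unname(sds),
    percent_of_baseline = 100 * unname(means) / base,
    stringsAsFactors = FALSE
  )
  structure(out, baseline_label = baseline_label,
            class = c("flow_series", "data.frame"))
}

#' @export
print.flow_series <- function(x, ...) {
  cat("<flow_series> baseline = \"", attr(x, "baseline_label"), "\"\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot percent-of-baseline flow over timepoints
#'
#' @param x A `flow_series`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.flow_series <- function(x, ...) {
  n <- nrow(x)
  graphics::plot(seq_len(n), x$percent_of_baseline, type = "b", pch = 19,
                 xaxt = "n", xlab = "timepoint",
                 ylab = "blood flow (% of baseline)", ...)
  graphics::axis(1, at = seq_len(n), labels = x$timepoint)
  graphics::abline(h = c(100, 80), lty = c(1, 2), col = "grey50")
  invisible(x)
}

#' Classify a flow time series as physiological, reversible or irreversible
#'
#' Applies the perfusion-safety rule: blood-flow changes of no more than
#' `threshold_percent` (default 20%) of baseline are physiologically
#' normal. A series is
#' * `"physiological"` if every timepoint stays at or above
#'   `100 - threshold` percent of baseline (the boundary is inclusive:
#'   exactly 80% still counts as normal),
#' * `"reversible-drop"` if some intermediate timepoint falls below the
#'   limit but the final timepoint has recovered to at or above it,
#' * `"irreversible-drop"` if the final timepoint is below the limit.
#'
#' @param series A `flow_series`, or a named numeric vector of
#'   percent-of-baseline values.
#' @param threshold_percent Allowed drop in percent, in (0, 100);
#'   default 20.
#' @param final_label Label of the final (persistence-defining) timepoint,
#'   e.g. `"24 h"`; must be present.
#' @return A `safety_label`: list with `label` and `threshold_percent`.
#' @examples
#' classify_flow_response(c(baseline = 100, `15 min` = 47, `24 h` = 53),
#'                        final_label = "24 h")
#' @export
classify_flow_response <- function(series, threshold_percent = 20,
                                   final_label) {
  check_scalar_num(threshold_percent, "threshold_percent", lower = 0,
                   upper = 100, strict_lower = TRUE)
  if (threshold_percent >= 100) {
    stop("`threshold_percent` must be in (0, 100)", call. = FALSE)
  }
  if (inherits(series, "flow_series")) {
    pct <- stats::setNames(series$percent_of_baseline, series$timepoint)
  } else {
    pct <- unlist(series)
  }
  if (is.null(names(pct))) {
    stop("`series` must carry timepoint names", call. = FALSE)
  }
  if (missing(final_label) || !final_label %in% names(pct)) {
    stop("final timepoint label ",
         if (missing(final_label)) "is required" else
           paste0("\"", final_label, "\" not found in the series"),
         call. = FALSE)
  }
  cut <- 100 - threshold_percent
  below <- pct < cut
  label <- if (below[[final_label]]) {
    "irreversible-drop"
  } else if (any(below)) {
    "reversible-drop"
  } else {
    "physiological"
  }
  structure(list(label = label, threshold_percent = threshold_percent),
            class = "safety_label")
}

#' @export
print.safety_label <- function(x, ...) {
  cat(sprintf("<safety_label> %s (threshold %g%%)\n", x$label,
              x$threshold_percent))
  invisible(x)
}

#' Relative change between two positive quantities, in percent
#'
#' `100 * (new - old) / reference`, with the reference either the old or
#' the new value. Used for headline trade-off statements such as "a 29%
#' larger capsule diameter (3.1 to 4.0 um) requires at least a 50% lower
#' dose (20e6 to 10e6)".
#'
#' @param old_value,new_value Positive quantities (vectorized).
#' @param reference `"old"` (default) or `"new"`: which value the change is
#'   expressed relative to.
#' @return Percent change, full precision (round only for display).
#' @examples
#' relative_change(3.1, 4.0)        # +29.0
#' relative_change(20e6, 10e6)      # -50
#' @export
relative_change <- function(old_value, new_value,
                            reference = c("old", "new")) {
  reference <- match.arg(reference)
  if (any(old_value <= 0) || any(new_value <= 0)) {
    stop("both values must be > 0", call. = FALSE)
  }
  ref <- if (reference == "old") old_value else new_value
  100 * (new_value - old_value) / ref
}

#' Percent-of-baseline flow series for a whole simulated experiment
#'
#' Runs [lsci_pipeline()] on every movie of a [simulate_flow_experiment()]
#' result and normalizes the ROI means to the baseline timepoint.
#'
#' @param experiment A `flow_experiment`.
#' @inheritParams lsci_pipeline
#' @return A `flow_series` (see [normalize_to_baseline()]).
#' @export
lsci_experiment_series <- function(experiment, window_px = 5,
                                   n_average = 25, sigma_px = 7,
                                   roi = NULL) {
  stopifnot(inherits(experiment, "flow_experiment"))
  res <- lapply(experiment$movies, lsci_pipeline, window_px = window_px,
                n_average = n_average, sigma_px = sigma_px, roi = roi)
  normalize_to_baseline(
    vapply(res, `[[`, numeric(1), "mean"),
    baseline_label = experiment$baseline_label,
    sds = vapply(res, `[[`, numeric(1), "sd")
  )
}
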