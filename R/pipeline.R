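## End-to-end orchestration from a single YAML/list config, plus the
## dose-size safety aggregation

config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages on synthetic inputs with explicit seeds
#' and writes all tables plus a JSON report. Stages:
#'
#' * `lsci`: [simulate_flow_experiment()] -> [lsci_experiment_series()] ->
#'   [classify_flow_response()]; writes `flow_series.csv`.
#' * `pa`: [simulate_pa_signal()] per timepoint ->
#'   [band_split_intensity()] -> [alteration_timecourse()]; writes
#'   `pa_alteration.csv`.
#' * `biodist`: [simulate_organ_tables()] -> [correct_organ_table()] ->
#'   [percent_id_from_tre()]; writes `percent_id.csv`.
#' * `plate`: [simulate_fluorimetry_plate()] -> [quantify_plate()] ->
#'   [percent_id_injected()]; writes `plate_masses.csv` and
#'   `calibration.json`.
#'
#' An empty `stages` list is a valid no-op producing an empty report.
#' Identical config and seeds produce byte-identical outputs.
#'
#' @param config A nested list, or path to a YAML file (see
#'   `system.file("extdata", "demo-config.yaml", package = "renoperf")`).
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$output_dir`, or no file output when both are `NULL`.
#' @return Invisibly, a list with per-stage results and the `report`
#'   (config hash, versions, stage summaries).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$output_dir
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% intersect(
    c("lsci", "pa", "biodist", "plate"), names(config))
  results <- list()
  summaries <- list()
  put <- function(df, file) {
    if (write_out) utils::write.csv(df, file.path(out_dir, file),
                                    row.names = FALSE)
  }

  for (stage in stages) {
    blk <- config[[stage]]
    if (is.null(blk)) {
      stop("stage \"", stage, "\" requested but its config block is missing",
           call. = FALSE)
    }
    if (stage == "lsci") {
      sp <- blk$speckle %||% list()
      cfg <- speckle_config(
        frame_height = sp$frame_height %||% 128,
        frame_width = sp$frame_width %||% 128,
        n_frames = sp$n_frames %||% 25,
        exposure_ms = sp$exposure_ms %||% 10,
        fps = sp$fps %||% 30,
        beta = sp$beta %||% 1,
        speckle_grain_px = sp$speckle_grain_px %||% 2
      )
      roi <- if (!is.null(blk$roi)) {
        do.call(roi_spec, blk$roi)
      } else NULL
      exper <- simulate_flow_experiment(
        baseline_tau_c_ms = blk$baseline_tau_c_ms,
        relative_flows = blk$relative_flows, cfg = cfg,
        seed = blk$seed
      )
      series <- lsci_experiment_series(
        exper, window_px = blk$window_px %||% 5,
        n_average = blk$n_average %||% cfg$n_frames,
        sigma_px = blk$sigma_px %||% 7, roi = roi
      )
      label <- classify_flow_response(
        series, threshold_percent = blk$threshold_percent %||% 20,
        final_label = blk$final_label
      )
      put(as.data.frame(series), "flow_series.csv")
      results$lsci <- list(series = series, label = label,
                           truth = exper$true_relative_flow)
      summaries$lsci <- list(
        label = label$label,
        percent_of_baseline = stats::setNames(
          as.list(round(series$percent_of_baseline, 6)), series$timepoint)
      )
    } else if (stage == "pa") {
      tps <- blk$timepoints
      sigs <- lapply(names(tps), function(tp) {
        amp <- unlist(tps[[tp]])
        simulate_pa_signal(
          amp_low = amp[1], amp_high = amp[2],
          fs = blk$fs_hz %||% 4e8, duration = blk$duration_s %||% 2e-5,
          timepoint_label = tp,
          seed = if (is.null(blk$seed)) NULL else
            blk$seed + match(tp, names(tps)) - 1L
        )
      })
      intens <- do.call(rbind, lapply(sigs, band_split_intensity))
      alt <- alteration_timecourse(intens,
                                   reference_label = blk$reference %||% "before")
      out <- merge(intens, alt, by = c("timepoint", "band"), sort = FALSE)
      put(out, "pa_alteration.csv")
      results$pa <- out
      summaries$pa <- list(timepoints = length(sigs))
    } else if (stage == "biodist") {
      tabs <- simulate_organ_tables(
        true_percent_id = blk$true_percent_id,
        autofl_per_area = blk$autofl_per_area %||% 1,
        areas = blk$areas, noise_cv = blk$noise_cv %||% 0.05,
        signal_total = blk$signal_total, seed = blk$seed
      )
      corrected <- correct_organ_table(tabs$experimental, tabs$control)
      pid <- percent_id_from_tre(corrected)
      pid_out <- pid
      pid_out$true_percent_id <- unname(tabs$truth[pid$organ])
      put(pid_out, "percent_id.csv")
      results$biodist <- list(tables = tabs, percent_id = pid)
      summaries$biodist <- list(
        organs = nrow(pid), total_tre = attr(pid, "total_tre"))
    } else if (stage == "plate") {
      plate <- simulate_fluorimetry_plate(
        standard_masses = unlist(blk$standard_masses),
        sample_masses = unlist(blk$sample_masses),
        slope = blk$slope, intercept = blk$intercept %||% 0,
        noise_sd = blk$noise_sd %||% 0, seed = blk$seed
      )
      q <- quantify_plate(plate)
      if (!is.null(blk$injected_mass)) {
        q$masses$percent_id <- percent_id_injected(q$masses$mass_est,
                                                   blk$injected_mass)
      }
      put(q$masses, "plate_masses.csv")
      if (write_out) {
        jsonlite::write_json(
          q$curve[c("slope", "intercept", "r_squared", "wavelength_nm")],
          file.path(out_dir, "calibration.json"),
          auto_unbox = TRUE, digits = NA)
      }
      results$plate <- q
      summaries$plate <- list(r_squared = q$curve$r_squared,
                              samples = nrow(q$masses))
    } else {
      stop("unknown stage \"", stage, "\"", call. = FALSE)
    }
  }

  report <- list(
    package = "renoperf",
    version = as.character(utils::packageVersion("renoperf")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash(config),
    stages = if (length(summaries)) summaries else list()
  )
  if (write_out) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    md <- c(
      "# renoperf run report", "",
      paste0("- config hash: ", report$config_hash),
      paste0("- stages run: ",
             if (length(summaries)) paste(names(summaries), collapse = ", ")
             else "(none)")
    )
    if (!is.null(summaries$lsci)) {
      md <- c(md, paste0("- flow outcome: ", summaries$lsci$label,
                         " (percent of baseline, rounded: ",
                         paste(sprintf("%s = %d%%",
                                       names(summaries$lsci$percent_of_baseline),
                                       round(unlist(summaries$lsci$percent_of_baseline))),
                               collapse = ", "), ")"))
    }
    writeLines(md, file.path(out_dir, "report.md"))
  }
  invisible(list(results = results, report = report))
}

#' Dose-size safety summary
#'
#' Labels each capsule dose group by its flow outcome and extracts the
#' headline trade-off: the relative change in capsule diameter between the
#' two sizes versus the relative change between their largest safe doses
#' (safe = not classified `irreversible-drop`). Groups whose flow outcome
#' is unknown (`NA` percentages) are kept in the table but excluded from
#' the safe-dose search.
#'
#' @param groups Data frame with columns `diameter_um`, `dose`,
#'   `percent_15min`, `percent_24h` (percent of baseline; `NA` = outcome
#'   not measured).
#' @param threshold_percent Safety threshold (default 20).
#' @return List with `table` (groups + `label`) and `comparison` (one row
#'   per ordered size pair: `diameter_change_percent`,
#'   `dose_change_percent`, both relative to the smaller size); the
#'   comparison is empty with fewer than two labelled sizes.
#' @examples
#' g <- data.frame(diameter_um = c(3.1, 4.0, 4.0),
#'                 dose = c(20e6, 10e6, 20e6),
#'                 percent_15min = c(85, 83, 47),
#'                 percent_24h = c(95, 92, 53))
#' dose_size_summary(g)$comparison
#' @export
dose_size_summary <- function(groups, threshold_percent = 20) {
  stopifnot(is.data.frame(groups), nrow(groups) >= 1,
            all(c("diameter_um", "dose", "percent_15min", "percent_24h")
                %in% names(groups)))
  groups$label <- vapply(seq_len(nrow(groups)), function(i) {
    p15 <- groups$percent_15min[i]
    p24 <- groups$percent_24h[i]
    if (is.na(p15) || is.na(p24)) return(NA_character_)
    classify_flow_response(
      c(baseline = 100, `15 min` = p15, `24 h` = p24),
      threshold_percent = threshold_percent, final_label = "24 h"
    )$label
  }, character(1))

  safe <- groups[!is.na(groups$label) &
                   groups$label != "irreversible-drop", , drop = FALSE]
  sizes <- sort(unique(safe$diameter_um))
  comparison <- data.frame(
    diameter_small_um = numeric(0), diameter_large_um = numeric(0),
    safe_dose_small = numeric(0), safe_dose_large = numeric(0),
    diameter_change_percent = numeric(0), dose_change_percent = numeric(0)
  )
  if (length(sizes) >= 2) {
    pairs <- utils::combn(sizes, 2)
    comparison <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      d1 <- pairs[1, j]; d2 <- pairs[2, j]
      dose1 <- max(safe$dose[safe$diameter_um == d1])
      dose2 <- max(safe$dose[safe$diameter_um == d2])
      data.frame(
        diameter_small_um = d1, diameter_large_um = d2,
        safe_dose_small = dose1, safe_dose_large = dose2,
        diameter_change_percent = relative_change(d1, d2),
        dose_change_percent = relative_change(dose1, dose2)
      )
    }))
  }
  list(table = groups, comparison = comparison)
}
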