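## File interchange: TIFF stacks + JSON sidecars for speckle movies,
## CSV for organ tables, acoustic traces and plates

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a speckle movie as a 16-bit multi-page TIFF with JSON sidecar
#'
#' Frames are scaled by the movie maximum into the 16-bit range; the scale
#' factor and acquisition metadata (`exposure_ms`, `fps`, `tau_c_ms`,
#' `seed`) go into a JSON sidecar next to the TIFF so the movie
#' round-trips through disk.
#'
#' @param movie A `speckle_movie`.
#' @param path Output TIFF path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_speckle_movie <- function(movie, path) {
  stopifnot(inherits(movie, "speckle_movie"))
  scale <- max(movie$frames)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(movie$frames)[1]), function(i) {
    movie$frames[i, , ] / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  cfg <- movie$provenance
  meta <- list(
    exposure_ms = movie$exposure_ms, fps = movie$fps, scale = scale,
    tau_c_ms = if (inherits(cfg, "speckle_config")) cfg$tau_c_ms else NULL,
    seed = if (inherits(cfg, "speckle_config")) cfg$seed else NULL
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a speckle movie written by [write_speckle_movie()]
#'
#' @param path TIFF path with a JSON sidecar alongside.
#' @return A `speckle_movie` with `provenance = "measured"` semantics: the
#'   sidecar metadata is kept as a plain list.
#' @export
read_speckle_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  scale <- meta$scale %||% 1
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                             ncol(pages[[1]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * scale
  structure(
    list(frames = frames, exposure_ms = meta$exposure_ms, fps = meta$fps,
         provenance = meta),
    class = "speckle_movie"
  )
}

#' Write / read an organ fluorescence table
#'
#' CSV with columns `organ`, `tre`, `area`, `group`.
#'
#' @param table Data frame with those columns.
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_organ_table <- function(table, path) {
  stopifnot(all(c("organ", "tre", "area", "group") %in% names(table)))
  utils::write.csv(table[, c("organ", "tre", "area", "group")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_organ_table
#' @export
read_organ_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("organ", "tre", "area", "group")
  if (!all(need %in% names(tb))) {
    stop("organ table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tb
}

#' Write / read an acoustic trace as CSV
#'
#' Columns `t` (seconds) and `amplitude`; the sampling rate is recovered
#' from the time column on read.
#'
#' @param signal A [pa_signal()].
#' @param path CSV path.
#' @param timepoint_label Label attached on read.
#' @return `path` / a `pa_signal`.
#' @export
write_pa_signal <- function(signal, path) {
  stopifnot(inherits(signal, "pa_signal"))
  t <- (seq_along(signal$samples) - 1) / signal$fs
  utils::write.csv(data.frame(t = t, amplitude = signal$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_pa_signal
#' @export
read_pa_signal <- function(path, timepoint_label = "signal") {
  tb <- utils::read.csv(path)
  if (!all(c("t", "amplitude") %in% names(tb)) || nrow(tb) < 2) {
    stop("acoustic CSV must have columns t, amplitude", call. = FALSE)
  }
  fs <- 1 / mean(diff(tb$t))
  pa_signal(tb$amplitude, fs, timepoint_label)
}

#' Write / read a fluorimetry plate
#'
#' Wide CSV (first column `wavelength_nm`, one column per well) plus a
#' standards manifest CSV (`well`, `mass`).
#'
#' @param plate A `fluorimetry_plate`.
#' @param path Plate CSV path.
#' @param standards_path Manifest CSV path; defaults to
#'   `<path>_standards.csv`.
#' @return `path` / a `fluorimetry_plate` (without simulation ground
#'   truth).
#' @export
write_plate <- function(plate, path, standards_path = NULL) {
  standards_path <- standards_path %||%
    paste0(tools::file_path_sans_ext(path), "_standards.csv")
  wide <- data.frame(wavelength_nm = plate$wavelengths, plate$wells,
                     check.names = FALSE)
  utils::write.csv(wide, path, row.names = FALSE)
  utils::write.csv(
    data.frame(well = names(plate$standards),
               mass = unname(plate$standards)),
    standards_path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path, standards_path = NULL) {
  standards_path <- standards_path %||%
    paste0(tools::file_path_sans_ext(path), "_standards.csv")
  wide <- utils::read.csv(path, check.names = FALSE)
  if (names(wide)[1] != "wavelength_nm") {
    stop("plate CSV must start with a wavelength_nm column", call. = FALSE)
  }
  std <- utils::read.csv(standards_path, stringsAsFactors = FALSE)
  wells <- as.matrix(wide[, -1, drop = FALSE])
  well_ids <- colnames(wells)
  sample_ids <- unique(sub("_r[0-9]+$", "",
                           setdiff(well_ids, std$well)))
  sample_ids <- setdiff(sample_ids, std$well)
  sample_wells <- lapply(sample_ids, function(id) {
    grep(paste0("^", id, "_r[0-9]+$"), well_ids, value = TRUE)
  })
  names(sample_wells) <- sample_ids
  structure(
    list(wavelengths = wide$wavelength_nm, wells = wells,
         standards = stats::setNames(std$mass, std$well),
         sample_wells = sample_wells, truth = NULL),
    class = "fluorimetry_plate"
  )
}
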