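## LSCI processing chain: sliding-window speckle contrast -> frame
## averaging -> 1/K^2 flow index -> Gaussian smoothing -> ROI statistics

# symmetric (edge-duplicating) reflective row padding indices
reflect_idx <- function(n, p) c(p:1, 1:n, n:(n - p + 1))[seq_len(n + 2 * p)]

# w x w box sums over a reflectively padded matrix; output same size as m
box_sums <- function(m, w) {
  p <- (w - 1L) %/% 2L
  P <- m[reflect_idx(nrow(m), p), reflect_idx(ncol(m), p), drop = FALSE]
  cs <- rbind(0, apply(P, 2, cumsum))
  rows <- cs[(w + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- cbind(0, t(apply(rows, 1, cumsum)))
  cs2[, (w + 1):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - w), drop = FALSE]
}

#' Spatial speckle contrast in a sliding window
#'
#' Per-pixel speckle contrast `K = sd / mean` of the intensities in an
#' odd-sized sliding window (default 5 x 5), the quantity at the base of
#' all LSCI flow mapping. The standard deviation is the sample (n - 1)
#' estimator. Edges are handled by reflective padding so the output has the
#' same shape as the input. Pixels whose window mean falls below a guard
#' threshold (`1e-12 *` the frame maximum) are masked (`NA`).
#'
#' @param frame 2-D numeric matrix of non-negative intensities, at least as
#'   large as the window in both dimensions.
#' @param window_px Odd window side length (default 5).
#' @return A `contrast_map`: list with `values` (matrix, `NA` where
#'   masked), `mask` (logical matrix, `TRUE` = valid), `window_px`,
#'   `n_frames_averaged = 1`.
#' @examples
#' f <- matrix(rexp(64 * 64), 64)
#' k <- spatial_contrast(f)
#' mean(k$values)  # ~1 for negative-exponential intensities
#' @export
spatial_contrast <- function(frame, window_px = 5) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("`frame` must be a numeric matrix", call. = FALSE)
  }
  window_px <- check_count(window_px, "window_px", lower = 3L)
  if (window_px %% 2 == 0) {
    stop("`window_px` must be odd (got ", window_px, ")", call. = FALSE)
  }
  if (nrow(frame) < window_px || ncol(frame) < window_px) {
    stop("frame (", nrow(frame), " x ", ncol(frame),
         ") is smaller than the ", window_px, " x ", window_px, " window",
         call. = FALSE)
  }
  npix <- window_px^2
  s1 <- box_sums(frame, window_px)
  s2 <- box_sums(frame^2, window_px)
  mu <- s1 / npix
  v <- pmax(s2 - s1^2 / npix, 0) / (npix - 1)
  guard <- 1e-12 * max(frame)
  valid <- mu > guard
  if (!any(valid)) {
    warning("all window means are below the guard threshold; ",
            "contrast map is fully masked")
  }
  k <- sqrt(v) / mu
  k[!valid] <- NA_real_
  structure(
    list(values = k, mask = valid, window_px = window_px,
         n_frames_averaged = 1L),
    class = "contrast_map"
  )
}

#' Average consecutive contrast maps
#'
#' Element-wise mean of the first `n` contrast maps (default 25, the number
#' of consecutive contrast frames averaged to raise the signal-to-noise of
#' the flow map). A pixel masked in any input stays masked.
#'
#' @param maps List of `contrast_map`s of identical shape and window.
#' @param n Number of maps to average (default 25); `length(maps) >= n`.
#' @return A `contrast_map` with `n_frames_averaged = n`.
#' @export
average_contrast <- function(maps, n = 25) {
  n <- check_count(n, "n")
  if (!is.list(maps) || length(maps) < n) {
    stop("need at least n = ", n, " contrast maps (got ",
         length(maps), ")", call. = FALSE)
  }
  maps <- maps[seq_len(n)]
  if (!all(vapply(maps, inherits, logical(1), "contrast_map"))) {
    stop("`maps` must be a list of contrast_map objects", call. = FALSE)
  }
  dims <- lapply(maps, function(m) dim(m$values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("contrast maps have mismatched shapes", call. = FALSE)
  }
  acc <- maps[[1]]$values
  valid <- maps[[1]]$mask
  for (m in maps[-1]) {
    acc <- acc + m$values
    valid <- valid & m$mask
  }
  avg <- acc / n
  avg[!valid] <- NA_real_
  structure(
    list(values = avg, mask = valid, window_px = maps[[1]]$window_px,
         n_frames_averaged = n),
    class = "contrast_map"
  )
}

#' Convert a contrast map to a flow-index map
#'
#' Applies the conventional LSCI flow index `1/K^2` per pixel: at fixed
#' exposure, faster flow blurs the speckle, lowers K and raises `1/K^2`.
#' The index is a qualitative perfusion surrogate, not a velocity. Pixels
#' with `K = 0` (no measurable fluctuation) cannot be inverted; they are
#' masked and counted in a warning.
#'
#' @param map A `contrast_map` with at least one unmasked pixel.
#' @return A `flow_map`: list with `values`, `mask`, `sigma_smooth_px`
#'   (`NULL` until smoothed), `n_zero_contrast`.
#' @export
contrast_to_flow <- function(map) {
  stopifnot(inherits(map, "contrast_map"))
  if (!any(map$mask)) {
    stop("contrast map has no unmasked pixels", call. = FALSE)
  }
  zero <- map$mask & map$values == 0
  n_zero <- sum(zero, na.rm = TRUE)
  if (n_zero > 0) {
    warning(n_zero, " pixel(s) with zero contrast masked in flow conversion")
  }
  valid <- map$mask & !zero
  flow <- 1 / map$values^2
  flow[!valid] <- NA_real_
  structure(
    list(values = flow, mask = valid, sigma_smooth_px = NULL,
         n_zero_contrast = n_zero),
    class = "flow_map"
  )
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# separable 1-D convolution along rows with reflective padding
conv_rows_reflect <- function(m, kern) {
  r <- (length(kern) - 1L) %/% 2L
  P <- m[reflect_idx(nrow(m), r), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kern)) {
    out <- out + kern[k] * P[(k - 1L) + seq_len(nrow(m)), , drop = FALSE]
  }
  out
}

#' Smooth a flow map with a spatial Gaussian filter
#'
#' Separable Gaussian convolution (default sigma 7 px, kernel truncated at
#' 4 sigma) with reflective boundaries, removing high-frequency speckle
#' residue so only coarse perfusion structure remains. On a fully unmasked
#' map the filter conserves the image total (the kernel is unit-sum and the
#' reflective boundary is symmetric). Masked pixels are handled by
#' normalized convolution: values are smoothed with mask weights so masked
#' regions neither bleed zeros into their surroundings nor receive values.
#'
#' @param map A `flow_map` (or `contrast_map`) to smooth.
#' @param sigma_px Gaussian sigma in pixels (> 0, default 7).
#' @return A `flow_map` with `sigma_smooth_px` set.
#' @export
smooth_flow <- function(map, sigma_px = 7) {
  stopifnot(inherits(map, "flow_map") || inherits(map, "contrast_map"))
  check_scalar_num(sigma_px, "sigma_px", lower = 0, strict_lower = TRUE)
  kern <- gaussian_kernel_1d(sigma_px)
  vals <- map$values
  w <- map$mask * 1
  vals[!map$mask] <- 0
  num <- conv_rows_reflect(t(conv_rows_reflect(t(vals * w), kern)), kern)
  den <- conv_rows_reflect(t(conv_rows_reflect(t(w), kern)), kern)
  sm <- num / den
  sm[!map$mask] <- NA_real_
  structure(
    list(values = sm, mask = map$mask, sigma_smooth_px = sigma_px,
         n_zero_contrast = map$n_zero_contrast %||% 0L),
    class = "flow_map"
  )
}

#' Rectangular region of interest
#'
#' A half-open pixel rectangle given by its top-left corner (1-based row
#' and column) and extents. The default 200 x 200 matches the ROI drawn on
#' the kidney flow maps.
#'
#' @param row,col 1-based top-left pixel indices (>= 1).
#' @param height,width ROI extents in pixels (>= 1; default 200).
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(row = 1, col = 1, height = 200, width = 200) {
  structure(
    list(row = check_count(row, "row"), col = check_count(col, "col"),
         height = check_count(height, "height"),
         width = check_count(width, "width")),
    class = "roi_spec"
  )
}

#' Mean and standard deviation of a map inside an ROI
#'
#' Arithmetic mean and sample standard deviation over the unmasked pixels
#' of the ROI.
#'
#' @param map A `flow_map` or `contrast_map`.
#' @param roi An [roi_spec()]; must lie fully inside the map and contain at
#'   least 2 unmasked pixels.
#' @return List with `mean` and `sd`.
#' @export
roi_statistics <- function(map, roi) {
  stopifnot(inherits(map, "flow_map") || inherits(map, "contrast_map"),
            inherits(roi, "roi_spec"))
  d <- dim(map$values)
  r1 <- roi$row + roi$height - 1L
  c1 <- roi$col + roi$width - 1L
  if (r1 > d[1] || c1 > d[2]) {
    stop("ROI [", roi$row, ":", r1, ", ", roi$col, ":", c1,
         "] extends beyond the ", d[1], " x ", d[2], " map", call. = FALSE)
  }
  px <- map$values[roi$row:r1, roi$col:c1]
  px <- px[!is.na(px)]
  if (length(px) < 2) {
    stop("ROI contains fewer than 2 unmasked pixels", call. = FALSE)
  }
  list(mean = mean(px), sd = stats::sd(px))
}

#' Run the full LSCI chain on one speckle movie
#'
#' Convenience wrapper applying the processing order used throughout the
#' package: per-frame sliding-window contrast, average of the first
#' `n_average` contrast maps, conversion to the `1/K^2` flow index,
#' Gaussian smoothing, and ROI statistics.
#'
#' @param movie A `speckle_movie` (or 3-D array frame x row x col).
#' @param window_px Contrast window (default 5).
#' @param n_average Contrast frames averaged (default 25).
#' @param sigma_px Smoothing sigma (default 7).
#' @param roi An [roi_spec()]; default: 200 x 200 centered in the frame
#'   (an error if the frame is smaller — pass an explicit ROI then).
#' @return List with `mean`, `sd`, the smoothed `flow_map`, the averaged
#'   `contrast_map` and the `roi` used.
#' @seealso [normalize_to_baseline()], [classify_flow_response()]
#' @export
lsci_pipeline <- function(movie, window_px = 5, n_average = 25,
                          sigma_px = 7, roi = NULL) {
  frames <- if (inherits(movie, "speckle_movie")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3)
  d <- dim(frames)
  if (d[1] < n_average) {
    stop("movie has ", d[1], " frames; n_average = ", n_average,
         " requires at least that many", call. = FALSE)
  }
  if (is.null(roi)) {
    if (d[2] < 200 || d[3] < 200) {
      stop("frames are ", d[2], " x ", d[3], " px; the default 200 x 200 ",
           "ROI does not fit — supply `roi`", call. = FALSE)
    }
    roi <- roi_spec(floor((d[2] - 200) / 2) + 1, floor((d[3] - 200) / 2) + 1)
  }
  maps <- lapply(seq_len(n_average), function(i) {
    spatial_contrast(frames[i, , ], window_px)
  })
  kbar <- average_contrast(maps, n_average)
  flow <- smooth_flow(contrast_to_flow(kbar), sigma_px)
  stats <- roi_statistics(flow, roi)
  list(mean = stats$mean, sd = stats$sd, flow_map = flow,
       contrast_map = kbar, roi = roi)
}
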