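# Perimeter and transect intensity profiling with modal background correction.

#' Modal background intensity of a channel raster
#'
#' Estimates section background as the mode of the integer-binned intensity
#' histogram over non-saturated pixels (value strictly below
#' `saturation_level`). Bin width is 1 intensity unit, matching integer-valued
#' acquisition rasters.
#'
#' @param raster Numeric matrix of intensities.
#' @param saturation_level Pixels at or above this value are excluded.
#' @return The modal intensity (scalar). Ties break toward the lowest value.
#' @examples
#' estimate_modal_background(matrix(c(50, 50, 50, 80), 2))
#' @export
estimate_modal_background <- function(raster, saturation_level = 65535) {
  if (length(raster) == 0) stop("empty raster", call. = FALSE)
  v <- round(as.numeric(raster))
  v <- v[v < saturation_level]
  if (length(v) == 0) {
    stop("all pixels saturated; cannot estimate background", call. = FALSE)
  }
  tab <- tabulate(v - min(v) + 1L)
  (which.max(tab) - 1L) + min(v)
}

#' Background-correct an intensity profile
#'
#' Subtracts a per-channel section background from raw profile intensities,
#' flooring at zero. Idempotent once the post-correction mode is zero.
#'
#' @param profile A long profile tibble with columns `channel` and `raw` (as
#'   returned by [extract_perimeter_profile()]).
#' @param background Named numeric vector of per-channel background levels
#'   (names matching `profile$channel`); must be non-negative.
#' @return The profile with a `corrected` column, `max(raw - background, 0)`.
#' @export
correct_profile <- function(profile, background) {
  stopifnot(all(background >= 0))
  miss <- setdiff(unique(profile$channel), names(background))
  if (length(miss) > 0) {
    stop("no background for channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(profile,
                corrected = unname(pmax(.data$raw -
                                          background[.data$channel], 0)))
}

#' Perimeter intensity profile of a fiber section
#'
#' Samples every channel along the fiber boundary at equal arc-length steps.
#' The intensity at each sample is the mean of the channel over an
#' inward-normal band of depth `band_depth_px` (band averaging makes the
#' profile robust to single-pixel noise; the inward normal comes from the
#' local boundary tangent). The profile closes cyclically: the last sample is
#' adjacent to the first.
#'
#' @param section A `fiber_section` (see [simulate_cohort()], [read_section()]).
#' @param step_px Arc-length distance between samples (pixels).
#' @param band_depth_px Depth of the averaged inward band (pixels).
#' @return A tibble with columns `fiber_id`, `idx`, `arc_fraction`, `channel`,
#'   `raw`; total perimeter length (px) in attribute `perimeter_px`.
#' @export
extract_perimeter_profile <- function(section, step_px = 1, band_depth_px = 10) {
  stopifnot(inherits(section, "fiber_section"), !is.null(section$channels))
  poly <- section$boundary
  per <- poly_perimeter(poly)
  if (per < 4 * step_px) {
    stop("polygon perimeter too short for the requested step", call. = FALSE)
  }
  rs <- poly_resample(poly, step_px)
  offs <- seq(0.5, band_depth_px, by = 1)
  n_s <- nrow(rs$points)
  dims <- dim(section$channels[[1]])
  # band sample coordinates: n_samples x n_offsets
  bx <- outer(rs$points[, 1], rep(1, length(offs))) +
    outer(rs$normal[, 1], offs)
  by <- outer(rs$points[, 2], rep(1, length(offs))) +
    outer(rs$normal[, 2], offs)
  clipped <- any(bx < 0 | bx > dims[2] - 1 | by < 0 | by > dims[1] - 1)
  if (clipped) {
    warning("perimeter band exits the raster; samples clipped to the edge",
            call. = FALSE)
  }
  prof <- purrr::imap(section$channels, function(raster, chan) {
    vals <- matrix(bilinear(raster, as.numeric(bx), as.numeric(by)),
                   n_s, length(offs))
    tibble::tibble(fiber_id = section$fiber_id, idx = seq_len(n_s),
                   arc_fraction = rs$frac, channel = chan,
                   raw = rowMeans(vals))
  })
  out <- dplyr::bind_rows(prof)
  attr(out, "perimeter_px") <- per
  out
}

#' Linear line scan across a section
#'
#' Samples every channel along the segment from `start` to `end` at (near)
#' unit spacing using bilinear interpolation, optionally subtracting a
#' per-channel background (floored at zero).
#'
#' @param section A `fiber_section`.
#' @param start,end Numeric length-2 pixel coordinates `(x, y)`, 0-based; must
#'   lie inside the raster.
#' @param background Optional named per-channel background to subtract.
#' @return A tibble: `distance_px`, `channel`, `raw` and (if background given)
#'   `corrected`. The number of samples is `ceiling(length) + 1`.
#' @export
extract_line_scan <- function(section, start, end, background = NULL) {
  stopifnot(inherits(section, "fiber_section"), !is.null(section$channels))
  dims <- dim(section$channels[[1]])
  for (pt in list(start, end)) {
    if (length(pt) != 2 || pt[1] < 0 || pt[1] > dims[2] - 1 ||
        pt[2] < 0 || pt[2] > dims[1] - 1) {
      stop("line scan endpoints must lie inside the raster", call. = FALSE)
    }
  }
  len <- sqrt(sum((end - start)^2))
  n <- as.integer(ceiling(len)) + 1L
  t_seq <- if (n == 1) 0 else seq(0, 1, length.out = n)
  xs <- start[1] + t_seq * (end[1] - start[1])
  ys <- start[2] + t_seq * (end[2] - start[2])
  out <- dplyr::bind_rows(purrr::imap(section$channels, function(raster, chan) {
    tibble::tibble(distance_px = t_seq * len, channel = chan,
                   raw = bilinear(raster, xs, ys))
  }))
  if (!is.null(background)) out <- correct_profile(out, background)
  out
}

#' Background-corrected perimeter profiles for a whole cohort
#'
#' For each fiber section, estimates per-channel modal background from the
#' section rasters, extracts the perimeter band profile and background-corrects
#' it.
#'
#' @param sections List of `fiber_section` objects.
#' @param config An [analysis_config()].
#' @return A long tibble: `fiber_id`, `idx`, `arc_fraction`, `channel`, `raw`,
#'   `corrected`, `perimeter_px`.
#' @export
profile_cohort <- function(sections, config = analysis_config()) {
  stopifnot(length(sections) > 0)
  dplyr::bind_rows(purrr::map(sections, function(sec) {
    bg <- vapply(sec$channels, estimate_modal_background,
                 numeric(1), saturation_level = config$saturation_level)
    prof <- extract_perimeter_profile(sec, config$sampling_step_px,
                                      config$band_depth_px)
    prof <- correct_profile(prof, bg)
    prof$perimeter_px <- attr(prof, "perimeter_px")
    prof
  }))
}
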