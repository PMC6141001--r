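# File formats: multi-channel TIFF sections, tabular ROI / ground-truth /
# annotation / plate files (CSV), JSON config and reports.
#
# Conventions: pixel coordinates are 0-based (x = column, y = row); ROI
# polygons are listed one vertex per row in boundary order with the closing
# edge implicit; arc positions are fractions of total perimeter in [0, 1),
# with the origin at the polygon's first vertex.

CHANNEL_ORDER <- c("dapi", "sdha", "mtcoi")

#' Write fiber sections to TIFF images and an ROI table
#'
#' Each section becomes one multi-page 16-bit TIFF (page order DAPI, SDHA,
#' MTCOI; intensities stored as value/65535) named `<fiber_id>.tif`, and all
#' boundary polygons go to one `rois.csv` (columns `image`, `fiber_id`,
#' `patient_id`, `section_id`, `vertex`, `x`, `y`).
#'
#' @param sections List of `fiber_section` objects with rendered channels.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the ROI table.
#' @export
write_sections <- function(sections, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rois <- lapply(sections, function(sec) {
    img <- paste0(sec$fiber_id, ".tif")
    if (!is.null(sec$channels)) {
      pages <- lapply(CHANNEL_ORDER, function(ch) sec$channels[[ch]] / 65535)
      tiff::writeTIFF(pages, file.path(dir, img), bits.per.sample = 16)
    }
    tibble::tibble(image = img, fiber_id = sec$fiber_id,
                   patient_id = sec$patient_id, section_id = sec$section_id,
                   vertex = seq_len(nrow(sec$boundary)),
                   x = sec$boundary[, 1], y = sec$boundary[, 2])
  })
  path <- file.path(dir, "rois.csv")
  readr::write_csv(dplyr::bind_rows(rois), path)
  invisible(path)
}

validate_boundary <- function(poly, fiber_id) {
  n0 <- nrow(poly)
  poly <- poly_dedupe(poly)
  if (nrow(poly) < n0) {
    warning(sprintf("fiber %s: %d duplicate vertices removed", fiber_id,
                    n0 - nrow(poly)), call. = FALSE)
  }
  if (nrow(poly) < 8) {
    stop(sprintf("fiber %s: polygon has fewer than 8 distinct vertices",
                 fiber_id), call. = FALSE)
  }
  if (!poly_is_simple(poly)) {
    stop(sprintf("fiber %s: polygon is self-intersecting", fiber_id),
         call. = FALSE)
  }
  poly
}

#' Read fiber sections from a TIFF image and ROI table
#'
#' Reads a multi-page TIFF (pages interpreted in the order given by
#' `channels`) and the ROI polygons referencing it, returning one
#' `fiber_section` per polygon. Raises a format error when the page count
#' does not match the configured channels or a polygon is degenerate
#' (under 8 distinct vertices, or self-intersecting).
#'
#' @param image_path Path to the multi-page TIFF.
#' @param roi_path Path to the ROI CSV (see [write_sections()]).
#' @param channels Channel names in page order.
#' @return A list of `fiber_section` objects.
#' @export
read_section <- function(image_path, roi_path, channels = CHANNEL_ORDER) {
  pages <- tiff::readTIFF(image_path, all = TRUE)
  if (length(pages) != length(channels)) {
    stop(sprintf("%s: expected %d channels, found %d pages",
                 basename(image_path), length(channels), length(pages)),
         call. = FALSE)
  }
  rasters <- stats::setNames(lapply(pages, function(p) round(p * 65535)),
                             channels)
  rois <- readr::read_csv(roi_path, show_col_types = FALSE)
  if ("image" %in% names(rois)) {
    rois <- rois[rois$image == basename(image_path), ]
  }
  if (nrow(rois) == 0) {
    stop("ROI table references no polygon for ", basename(image_path),
         call. = FALSE)
  }
  rois |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::group_map(function(g, key) {
      g <- dplyr::arrange(g, .data$vertex)
      poly <- validate_boundary(poly_matrix(g$x, g$y), key$fiber_id)
      structure(list(
        patient_id = if ("patient_id" %in% names(g)) g$patient_id[1] else NA,
        section_id = if ("section_id" %in% names(g)) g$section_id[1] else NA,
        fiber_id = key$fiber_id, boundary = poly, channels = rasters,
        pixel_size = NULL), class = "fiber_section")
    })
}

#' Write and read simulation ground truth
#'
#' Ground truth is stored as three CSVs (`truth_fibers.csv`,
#' `truth_nuclei.csv`, `truth_foci.csv`) with one record per row.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param dir Directory.
#' @return `write_truth` returns the directory invisibly; `read_truth`
#'   returns the truth list.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(truth$fibers, file.path(dir, "truth_fibers.csv"))
  readr::write_csv(truth$nuclei, file.path(dir, "truth_nuclei.csv"))
  readr::write_csv(truth$foci, file.path(dir, "truth_foci.csv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  list(fibers = readr::read_csv(file.path(dir, "truth_fibers.csv"),
                                show_col_types = FALSE),
       nuclei = readr::read_csv(file.path(dir, "truth_nuclei.csv"),
                                show_col_types = FALSE),
       foci = readr::read_csv(file.path(dir, "truth_foci.csv"),
                              show_col_types = FALSE))
}

#' Read manual COX-deficiency annotations
#'
#' Manual annotations are arc-fraction intervals labelled COX-deficient:
#' columns `fiber_id`, `start_frac`, `end_frac` and optionally `label`
#' (defaults to `"COX-deficient"`; rows labelled `"COX-positive"` are
#' ignored). Intervals with `start_frac > end_frac` wrap across the arc
#' origin; overlapping intervals union. An empty file means every position is
#' COX-positive.
#'
#' @param path CSV path.
#' @return A tibble of deficient intervals (possibly zero rows).
#' @export
read_manual_annotation <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(ann) == 0) {
    return(tibble::tibble(fiber_id = character(), start_frac = numeric(),
                          end_frac = numeric()))
  }
  need <- c("fiber_id", "start_frac", "end_frac")
  if (!all(need %in% names(ann))) {
    stop("manual annotation needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- c(ann$start_frac, ann$end_frac)
  if (any(bad < 0 | bad >= 1)) {
    stop("arc fractions must lie in [0, 1)", call. = FALSE)
  }
  if ("label" %in% names(ann)) {
    ann <- ann[ann$label != "COX-positive", ]
  }
  tibble::as_tibble(ann[, intersect(c(need, "label"), names(ann))])
}

# Manual intervals -> focal mask on an n-sample grid (nearest-sample
# alignment via the half-open grid cells of mask_from_intervals).
manual_focal_mask <- function(ann, n_samples) {
  if (nrow(ann) == 0) return(logical(n_samples))
  mask_from_intervals(ann$start_frac, ann$end_frac, n_samples)
}

#' Plate CSV round trip
#'
#' @param plate Plate tibble (see [simulate_qpcr_plate()]).
#' @param path CSV path.
#' @return `write_plate_csv` returns `path` invisibly; `read_plate_csv` the
#'   plate tibble.
#' @export
write_plate_csv <- function(plate, path) {
  readr::write_csv(plate, path)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(fiber_id = readr::col_character(),
                                          region_id = readr::col_character()))
}

#' Read and write the analysis configuration as JSON
#'
#' @param config An [analysis_config()].
#' @param path JSON path.
#' @return `write_config` returns `path` invisibly; `read_config` an
#'   `analysis_config` built from the stored fields (missing fields take
#'   their defaults).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw[intersect(names(raw),
                                         names(formals(analysis_config)))])
}
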