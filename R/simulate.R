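# Synthetic fiber-section generator. Fibers are perturbed-ellipse polygons;
# nuclei are Gaussian DAPI blobs centered on the perimeter; a COX-deficient
# focus is a contiguous perimeter arc whose subsarcolemmal band has SDHA
# multiplied and MTCOI attenuated. Ground truth (nucleus arc positions, focus
# intervals) is returned alongside the images so detection can be scored.

# Point on the closed boundary at a given arc-length fraction.
point_at_fraction <- function(poly, frac) {
  per <- poly_perimeter(poly)
  s <- (frac %% 1) * per
  el <- poly_edge_lengths(poly)
  cum <- c(0, cumsum(el))
  e <- findInterval(s, cum, rightmost.closed = TRUE)
  e[e > nrow(poly)] <- nrow(poly)
  t_in <- (s - cum[e]) / el[e]
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  poly[e, , drop = FALSE] + t_in * (nxt[e, , drop = FALSE] - poly[e, , drop = FALSE])
}

# Irregular convex-ish boundary: radial perturbation of a circle by a few
# low-order harmonics. Returned centered on `center`.
make_fiber_polygon <- function(radius, irregularity, n_vertices, center) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- rep(radius, n_vertices)
  for (k in 2:4) {
    amp <- stats::runif(1, 0, irregularity) / (k - 1)
    phase <- stats::runif(1, 0, 2 * pi)
    r <- r * (1 + amp * sin(k * theta + phase))
  }
  poly_matrix(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

render_fiber_section <- function(poly, nuclei_frac, focus, p) {
  pad <- ceiling(3 * p$nucleus_sigma_px + 6)
  xmax <- max(poly[, 1]); ymax <- max(poly[, 2])
  w <- ceiling(xmax + pad) + 1L
  h <- ceiling(ymax + pad) + 1L
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  inside <- matrix(point_in_polygon(rep(xs, each = h), rep(ys, times = w), poly),
                   nrow = h, ncol = w)

  sdha <- p$channel_baseline[["sdha"]] * inside
  mtcoi <- p$channel_baseline[["mtcoi"]] * inside

  if (!is.null(focus)) {
    fm <- focus_band_mask(poly, focus$start_frac, focus$end_frac,
                          p$focus_depth_px, h, w)
    sdha[fm] <- sdha[fm] * p$sdha_focus_fold
    mtcoi[fm] <- mtcoi[fm] * p$mtcoi_focus_atten
  }

  dapi <- matrix(0, h, w)
  if (length(nuclei_frac) > 0) {
    centers <- point_at_fraction(poly, nuclei_frac)
    s2 <- 2 * p$nucleus_sigma_px^2
    for (i in seq_len(nrow(centers))) {
      gx <- exp(-(xs - centers[i, 1])^2 / s2)
      gy <- exp(-(ys - centers[i, 2])^2 / s2)
      dapi <- dapi + p$dapi_amplitude * outer(gy, gx)
    }
  }

  finish <- function(signal, chan) {
    v <- signal + p$background_level[[chan]]
    if (p$noise_sd[[chan]] > 0) {
      v <- v + stats::rnorm(length(v), 0, p$noise_sd[[chan]])
    }
    matrix(pmin(pmax(round(v), 0), p$saturation_level), nrow(signal), ncol(signal))
  }
  list(dapi = finish(dapi, "dapi"), sdha = finish(sdha, "sdha"),
       mtcoi = finish(mtcoi, "mtcoi"))
}

# Pixel mask of the subsarcolemmal band under a focus arc: dense stamping of
# boundary samples offset along the inward normal (0.25 px spacing leaves no
# holes after rounding to the pixel grid).
focus_band_mask <- function(poly, start_frac, end_frac, depth, h, w) {
  rs <- poly_resample(poly, 0.25)
  f <- rs$frac
  in_arc <- if (start_frac <= end_frac) {
    f >= start_frac & f < end_frac
  } else {
    f >= start_frac | f < end_frac
  }
  mask <- matrix(FALSE, h, w)
  pts <- rs$points[in_arc, , drop = FALSE]
  nrm <- rs$normal[in_arc, , drop = FALSE]
  for (off in seq(0, depth, by = 0.25)) {
    px <- round(pts[, 1] + off * nrm[, 1])
    py <- round(pts[, 2] + off * nrm[, 2])
    ok <- px >= 0 & px < w & py >= 0 & py < h
    mask[cbind(py[ok] + 1, px[ok] + 1)] <- TRUE
  }
  mask
}

#' Simulate a cohort of muscle-fiber cross-sections with known ground truth
#'
#' Generates `n_fibers` synthetic fiber sections: an irregular closed boundary
#' polygon, a DAPI channel with Gaussian blobs at perimeter nucleus positions,
#' and SDHA/MTCOI channels whose subsarcolemmal band is modified inside a
#' COX-deficient focus arc (SDHA multiplied by `sdha_focus_fold`, MTCOI by
#' `mtcoi_focus_atten`). Per-channel background and noise are added and values
#' clipped to `saturation_level`. With `enrichment_rho = 1` every focus is
#' seeded at a nucleus (perinuclear origin); with `enrichment_rho = 0` focus
#' centers are uniform on the perimeter (independence null).
#'
#' @param params A [cohort_sim_params()] object.
#' @param render If `FALSE`, skip image rendering and return ground truth with
#'   boundary polygons only (used for large calibration simulations where only
#'   the arc geometry matters).
#' @return A list of class `fiber_cohort` with elements
#'   \describe{
#'     \item{sections}{List of `fiber_section` objects (empty when
#'       `render = FALSE`): `patient_id`, `section_id`, `fiber_id`, `boundary`
#'       polygon and named `channels` rasters.}
#'     \item{truth}{Ground truth: tibbles `fibers` (ids, radius, perimeter,
#'       focus flags), `nuclei` (arc-length fractions) and `foci` (arc
#'       intervals, wraparound allowed, plus whether the focus was seeded at a
#'       nucleus).}
#'   }
#' @examples
#' coh <- simulate_cohort(cohort_sim_params(n_fibers = 2, seed = 7))
#' names(coh$sections[[1]]$channels)
#' coh$truth$foci
#' @export
simulate_cohort <- function(params = cohort_sim_params(), render = TRUE) {
  validate_cohort_sim_params(params)
  p <- params
  with_local_seed(p$seed, {
    sections <- list()
    fibers <- vector("list", p$n_fibers)
    nuclei <- vector("list", p$n_fibers)
    foci <- vector("list", p$n_fibers)
    patients <- paste0("P", ((seq_len(p$n_fibers) - 1) %% 3) + 1)
    for (i in seq_len(p$n_fibers)) {
      fid <- sprintf("F%03d", i)
      radius <- p$fiber_radius_px *
        stats::runif(1, 1 - p$radius_jitter, 1 + p$radius_jitter)
      rmax <- radius * (1 + 2 * p$boundary_irregularity)
      pad <- ceiling(3 * p$nucleus_sigma_px + 6)
      center <- c(rmax + pad, rmax + pad)
      poly <- make_fiber_polygon(radius, p$boundary_irregularity,
                                 p$n_vertices, center)
      n_nuc <- if (p$n_nuclei_range[1] == p$n_nuclei_range[2]) {
        p$n_nuclei_range[1]
      } else {
        sample(p$n_nuclei_range[1]:p$n_nuclei_range[2], 1)
      }
      nuc_frac <- sort(stats::runif(n_nuc))
      has_focus <- stats::runif(1) < p$foci_per_fiber_prob
      focus <- NULL
      if (has_focus) {
        at_nucleus <- n_nuc > 0 && stats::runif(1) < p$enrichment_rho
        center_frac <- if (at_nucleus) {
          nuc_frac[sample.int(n_nuc, 1)]
        } else {
          stats::runif(1)
        }
        half <- p$focus_arc_fraction / 2
        focus <- list(start_frac = (center_frac - half) %% 1,
                      end_frac = (center_frac + half) %% 1,
                      center_frac = center_frac, at_nucleus = at_nucleus)
        foci[[i]] <- tibble::tibble(
          fiber_id = fid, focus_id = paste0(fid, "_focus1"),
          start_frac = focus$start_frac, end_frac = focus$end_frac,
          center_frac = center_frac, at_nucleus = at_nucleus,
          contains_nucleus = n_nuc > 0 &&
            any(arc_distance(nuc_frac, center_frac) <= half))
      }
      if (n_nuc > 0) {
        nuclei[[i]] <- tibble::tibble(
          fiber_id = fid, nucleus_id = paste0(fid, "_n", seq_len(n_nuc)),
          arc_fraction = nuc_frac)
      }
      fibers[[i]] <- tibble::tibble(
        fiber_id = fid, patient_id = patients[i], section_id = paste0("S", i),
        radius_px = radius, perimeter_px = poly_perimeter(poly),
        n_nuclei = n_nuc, has_focus = has_focus)
      section <- structure(
        list(patient_id = patients[i], section_id = paste0("S", i),
             fiber_id = fid, boundary = poly,
             channels = if (render) {
               render_fiber_section(poly, nuc_frac, focus, p)
             } else {
               NULL
             },
             pixel_size = NULL),
        class = "fiber_section")
      sections[[i]] <- section
    }
    structure(
      list(sections = sections,
           truth = list(fibers = dplyr::bind_rows(fibers),
                        nuclei = dplyr::bind_rows(nuclei),
                        foci = dplyr::bind_rows(foci)),
           params = p),
      class = "fiber_cohort")
  })
}

#' Arc-domain annotations derived from simulation ground truth
#'
#' Builds perinuclear and focal perimeter masks directly from the generator's
#' ground truth, bypassing image rendering and detection: the perinuclear mask
#' covers an arc of `+/- halfwidth` (perimeter fraction) around each true
#' nucleus position, and the focal mask covers the true focus interval(s).
#' Useful for large calibration studies of the overlap statistic where the
#' quantity of interest is the placement geometry, not detection fidelity.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param n_samples Number of arc samples per fiber.
#' @param halfwidth Perinuclear half-width as a perimeter fraction (defaults
#'   to the generator's `perinuclear_halfwidth`).
#' @return A `domain_annotation` tibble: one row per fiber with list-columns
#'   `perinuclear` and `focal` (logical masks) and fractions `P`, `F`, `O_obs`.
#' @seealso [annotate_cohort()] for the image-based detection route.
#' @export
annotate_from_truth <- function(truth, n_samples = 400, halfwidth = 0.04) {
  stopifnot(n_samples >= 8)
  fibers <- truth$fibers
  res <- lapply(seq_len(nrow(fibers)), function(i) {
    fid <- fibers$fiber_id[i]
    nuc <- truth$nuclei[truth$nuclei$fiber_id == fid, , drop = FALSE]
    foc <- truth$foci[truth$foci$fiber_id == fid, , drop = FALSE]
    peri <- if (nrow(nuc) > 0) {
      mask_from_intervals(nuc$arc_fraction - halfwidth,
                          nuc$arc_fraction + halfwidth, n_samples)
    } else {
      logical(n_samples)
    }
    focal <- if (nrow(foc) > 0) {
      mask_from_intervals(foc$start_frac, foc$end_frac, n_samples)
    } else {
      logical(n_samples)
    }
    domain_annotation_row(fid, peri, focal)
  })
  dplyr::bind_rows(res)
}

# One DomainAnnotation record; P/F/O are recomputed from the masks so the
# invariants (P = mean(peri), O <= min(P, F)) hold by construction.
domain_annotation_row <- function(fiber_id, perinuclear, focal) {
  stopifnot(length(perinuclear) == length(focal))
  peri <- unname(as.logical(perinuclear))
  foc <- unname(as.logical(focal))
  tibble::tibble(
    fiber_id = fiber_id, n_samples = length(peri),
    perinuclear = list(peri), focal = list(foc),
    P = mean(peri), F = mean(foc), O_obs = mean(peri & foc))
}
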