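#' Simulation parameters for a synthetic fiber cohort
#'
#' Bundles every knob of the synthetic-section generator. Defaults emulate the
#' cross-sections analysed by the perimeter-profiling pipeline: irregular
#' roughly-convex fibers bearing 1-5 perimeter myonuclei, at most one
#' COX-deficient focus per fiber confined to a subsarcolemmal band, SDHA
#' elevated about 3.3-fold and MTCOI strongly attenuated inside the focus.
#'
#' @param n_fibers Number of fibers in the cohort (default 74, the size of the
#'   profiled cohort the pipeline is designed around).
#' @param fiber_radius_px Mean fiber radius in pixels.
#' @param radius_jitter Fractional jitter of the radius across fibers
#'   (each fiber's radius is uniform in `radius * (1 +/- jitter)`).
#' @param boundary_irregularity Amplitude of the low-order radial perturbation
#'   that makes boundaries irregular but still simple polygons.
#' @param n_vertices Vertices per boundary polygon.
#' @param n_nuclei_range Integer range (inclusive) of perimeter nuclei per fiber.
#' @param nucleus_sigma_px Standard deviation of the 2-D Gaussian DAPI blob
#'   rendered at each nucleus (pixels).
#' @param dapi_amplitude Peak DAPI signal of a nucleus blob above background.
#' @param enrichment_rho Probability in \[0, 1\] that a focus is seeded at a
#'   nucleus center rather than uniformly on the perimeter. `1` reproduces the
#'   perinuclear origin of foci; `0` is the independence null used for
#'   calibration.
#' @param foci_per_fiber_prob Probability a fiber carries a focus.
#' @param focus_arc_fraction Fraction of the perimeter covered by one focus
#'   (must lie in (0, 0.5)).
#' @param focus_depth_px Depth of the subsarcolemmal band affected by a focus.
#' @param sdha_focus_fold Multiplicative SDHA elevation inside foci
#'   (default 3.3, the mean focal elevation of the mitochondrial mass marker).
#' @param mtcoi_focus_atten Multiplicative MTCOI attenuation inside foci.
#' @param channel_baseline Named numeric: in-fiber SDHA and MTCOI signal.
#' @param background_level Named numeric: additive per-channel background.
#' @param noise_sd Named numeric: per-channel Gaussian noise SD.
#' @param perinuclear_halfwidth Half-width, as a perimeter fraction, of the
#'   perinuclear arc attributed to one nucleus when annotations are built
#'   directly from ground truth (see [annotate_from_truth()]).
#' @param saturation_level Maximum representable intensity (16-bit default).
#' @param seed Integer seed; a fixed seed makes the cohort bit-identical.
#' @return A `cohort_sim_params` list.
#' @seealso [simulate_cohort()]
#' @export
cohort_sim_params <- function(n_fibers = 74,
                              fiber_radius_px = 60,
                              radius_jitter = 0.15,
                              boundary_irregularity = 0.08,
                              n_vertices = 72,
                              n_nuclei_range = c(1L, 5L),
                              nucleus_sigma_px = 5,
                              dapi_amplitude = 600,
                              enrichment_rho = 1,
                              foci_per_fiber_prob = 1,
                              focus_arc_fraction = 0.2,
                              focus_depth_px = 10,
                              sdha_focus_fold = 3.3,
                              mtcoi_focus_atten = 0.1,
                              channel_baseline = c(sdha = 100, mtcoi = 100),
                              background_level = c(dapi = 40, sdha = 30, mtcoi = 30),
                              noise_sd = c(dapi = 5, sdha = 5, mtcoi = 5),
                              perinuclear_halfwidth = 0.04,
                              saturation_level = 65535,
                              seed = 1L) {
  p <- list(n_fibers = as.integer(n_fibers), fiber_radius_px = fiber_radius_px,
            radius_jitter = radius_jitter,
            boundary_irregularity = boundary_irregularity,
            n_vertices = as.integer(n_vertices),
            n_nuclei_range = as.integer(n_nuclei_range),
            nucleus_sigma_px = nucleus_sigma_px, dapi_amplitude = dapi_amplitude,
            enrichment_rho = enrichment_rho,
            foci_per_fiber_prob = foci_per_fiber_prob,
            focus_arc_fraction = focus_arc_fraction,
            focus_depth_px = focus_depth_px,
            sdha_focus_fold = sdha_focus_fold,
            mtcoi_focus_atten = mtcoi_focus_atten,
            channel_baseline = channel_baseline,
            background_level = background_level, noise_sd = noise_sd,
            perinuclear_halfwidth = perinuclear_halfwidth,
            saturation_level = saturation_level,
            seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_cohort_sim_params(p)
  structure(p, class = "cohort_sim_params")
}

validate_cohort_sim_params <- function(p) {
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
      stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
    }
  }
  if (p$n_fibers < 1) stop("`n_fibers` must be >= 1", call. = FALSE)
  if (p$fiber_radius_px <= 0) stop("`fiber_radius_px` must be positive", call. = FALSE)
  chk_prob(p$enrichment_rho, "enrichment_rho")
  chk_prob(p$foci_per_fiber_prob, "foci_per_fiber_prob")
  chk_prob(p$radius_jitter, "radius_jitter")
  if (p$focus_arc_fraction <= 0 || p$focus_arc_fraction >= 0.5) {
    stop("`focus_arc_fraction` must lie in (0, 0.5)", call. = FALSE)
  }
  if (p$sdha_focus_fold <= 0 || p$mtcoi_focus_atten <= 0) {
    stop("focus fold parameters must be positive", call. = FALSE)
  }
  if (length(p$n_nuclei_range) != 2 || p$n_nuclei_range[1] < 0 ||
      diff(p$n_nuclei_range) < 0) {
    stop("`n_nuclei_range` must be a non-decreasing integer pair", call. = FALSE)
  }
  for (nm in c("background_level", "noise_sd")) {
    v <- p[[nm]]
    if (!all(c("dapi", "sdha", "mtcoi") %in% names(v)) || any(v < 0)) {
      stop(sprintf("`%s` needs non-negative dapi/sdha/mtcoi entries", nm),
           call. = FALSE)
    }
  }
  invisible(p)
}

#' Simulation parameters for a triplex qPCR plate
#'
#' Cq values are generated from a log-linear standard-curve model,
#' `Cq = intercept + slope * log10(copies)`, with Gaussian replicate noise.
#' The default slope of -3.3219 cycles per log10 copies corresponds to a
#' perfectly efficient doubling per cycle.
#'
#' @param slope Standard-curve slope (cycles per log10 copies; must be < 0).
#' @param intercept Cq of a single template copy (cycles).
#' @param noise_sd Replicate Cq noise SD (cycles).
#' @param dilution_copies Strictly decreasing plasmid copies of the standard
#'   dilution series.
#' @param n_replicates Replicates per well group (default 3, triplicate).
#' @param ntc_cq Cq reported for no-template-control wells; `NA` encodes no
#'   amplification.
#' @param seed Integer seed for replicate noise.
#' @return A `qpcr_sim_params` list.
#' @seealso [simulate_qpcr_plate()]
#' @export
qpcr_sim_params <- function(slope = -3.3219,
                            intercept = 40,
                            noise_sd = 0.1,
                            dilution_copies = 10^(7:2),
                            n_replicates = 3L,
                            ntc_cq = 35,
                            seed = 1L) {
  if (slope >= 0) stop("`slope` must be negative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(dilution_copies) < 2 || any(diff(dilution_copies) >= 0)) {
    stop("`dilution_copies` must be strictly decreasing", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 dilution_copies = dilution_copies,
                 n_replicates = as.integer(n_replicates), ntc_cq = ntc_cq,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "qpcr_sim_params")
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the profiling, annotation, overlap and
#' qPCR stages in one declarative object.
#'
#' @param quantile_q Cohort quantile of corrected DAPI intensity defining the
#'   perinuclear threshold (default 0.85).
#' @param sampling_step_px Arc-length spacing of perimeter samples (pixels).
#' @param band_depth_px Depth of the inward band averaged at each sample.
#' @param saturation_level Intensity at/above which a pixel counts as
#'   saturated for modal background estimation.
#' @param min_run Minimum run length (samples) kept in perinuclear/focal masks.
#' @param deficiency_fraction A perimeter point is called COX-deficient when
#'   its MTCOI/SDHA ratio falls below this fraction of the fiber median ratio.
#' @param ratio_epsilon Small constant guarding the MTCOI/SDHA division.
#' @param deficient_cover Fraction of deficient samples at/above which a fiber
#'   is called fully COX-deficient.
#' @param focus_max_fraction Upper bound on the focal fraction for a fiber to
#'   count as carrying a focus (a focus is confined within an otherwise
#'   COX-positive fiber).
#' @param efficiency_bounds Admissible standard-curve amplification efficiency
#'   (fractions; default 95-100%).
#' @param ntc_margin_cycles Minimum number of cycles every region of a fiber
#'   group must sit below the ND1 no-template control.
#' @param dloop_tolerance_fold D-Loop/ND1 ratio above which an ND1-intact
#'   region is flagged.
#' @param alpha Significance level.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(quantile_q = 0.85,
                            sampling_step_px = 1,
                            band_depth_px = 10,
                            saturation_level = 65535,
                            min_run = 3L,
                            deficiency_fraction = 0.5,
                            ratio_epsilon = 1e-6,
                            deficient_cover = 0.95,
                            focus_max_fraction = 0.5,
                            efficiency_bounds = c(0.95, 1.00),
                            ntc_margin_cycles = 3,
                            dloop_tolerance_fold = 2,
                            alpha = 0.05) {
  if (quantile_q <= 0 || quantile_q >= 1) {
    stop("`quantile_q` must lie in (0, 1)", call. = FALSE)
  }
  if (sampling_step_px <= 0 || band_depth_px <= 0) {
    stop("step and band depth must be positive", call. = FALSE)
  }
  structure(list(quantile_q = quantile_q, sampling_step_px = sampling_step_px,
                 band_depth_px = band_depth_px,
                 saturation_level = saturation_level,
                 min_run = as.integer(min_run),
                 deficiency_fraction = deficiency_fraction,
                 ratio_epsilon = ratio_epsilon,
                 deficient_cover = deficient_cover,
                 focus_max_fraction = focus_max_fraction,
                 efficiency_bounds = efficiency_bounds,
                 ntc_margin_cycles = ntc_margin_cycles,
                 dloop_tolerance_fold = dloop_tolerance_fold,
                 alpha = alpha),
            class = "analysis_config")
}
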