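# Shared fixtures, built in code.

# A plain square fiber section (side px, 8 boundary vertices including edge
# midpoints) with constant channel rasters.
make_square_section <- function(side = 100, value = c(dapi = 50, sdha = 80,
                                                      mtcoi = 80),
                                origin = c(20, 20), pad = 40) {
  s <- side
  o <- origin
  poly <- cbind(
    x = o[1] + c(0, s / 2, s, s, s, s / 2, 0, 0),
    y = o[2] + c(0, 0, 0, s / 2, s, s, s, s / 2))
  dim_px <- ceiling(o + s + pad)
  channels <- lapply(value, function(v) matrix(v, dim_px[2], dim_px[1]))
  structure(list(patient_id = "P1", section_id = "S1", fiber_id = "SQ1",
                 boundary = poly, channels = channels, pixel_size = NULL),
            class = "fiber_section")
}

# Small zero-noise cohort shared by detection-fidelity tests (computed once).
zero_noise_cohort <- local({
  cache <- NULL
  function(n_fibers = 6, seed = 42) {
    if (is.null(cache)) {
      cache <<- simulate_cohort(cohort_sim_params(
        n_fibers = n_fibers, noise_sd = c(dapi = 0, sdha = 0, mtcoi = 0),
        seed = seed))
    }
    cache
  }
})

# Jaccard index between a detected mask and the ground-truth focus interval.
focus_jaccard <- function(annotation_row, foci_truth) {
  n <- annotation_row$n_samples
  truth_mask <- mitofoci:::mask_from_intervals(foci_truth$start_frac,
                                               foci_truth$end_frac, n)
  detected <- annotation_row$focal[[1]]
  if (!any(truth_mask | detected)) return(1)
  sum(truth_mask & detected) / sum(truth_mask | detected)
}

# Does the perinuclear mask contain the sample nearest to each true nucleus?
nuclei_recovered <- function(annotations, nuclei_truth) {
  mapply(function(fid, frac) {
    a <- annotations[annotations$fiber_id == fid, ]
    m <- a$perinuclear[[1]]
    m[(round(frac * a$n_samples) %% a$n_samples) + 1]
  }, nuclei_truth$fiber_id, nuclei_truth$arc_fraction)
}
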