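test_that("parameter validation rejects invalid probabilities and radii", {
  expect_error(cohort_sim_params(enrichment_rho = 1.2), "probability")
  expect_error(cohort_sim_params(foci_per_fiber_prob = -0.1), "probability")
  expect_error(cohort_sim_params(fiber_radius_px = 0), "positive")
  expect_error(cohort_sim_params(focus_arc_fraction = 0.6), "0, 0.5")
  expect_error(cohort_sim_params(n_fibers = 0), ">= 1")
  expect_error(qpcr_sim_params(slope = 0.5), "negative")
  expect_error(qpcr_sim_params(dilution_copies = c(10, 100)), "decreasing")
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  p <- cohort_sim_params(n_fibers = 2, seed = 31)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sections[[1]]$channels, b$sections[[1]]$channels)
  expect_identical(a$sections[[2]]$boundary, b$sections[[2]]$boundary)
})

test_that("fiber boundaries are simple closed polygons with perimeter nuclei", {
  coh <- zero_noise_cohort()
  for (sec in coh$sections) {
    expect_true(mitofoci:::poly_is_simple(sec$boundary))
    expect_gte(nrow(sec$boundary), 8)
  }
  # DAPI maxima sit at nucleus positions: raster value at the nucleus center
  # is close to the blob amplitude plus background
  sec <- coh$sections[[1]]
  nuc <- coh$truth$nuclei[coh$truth$nuclei$fiber_id == sec$fiber_id, ]
  ctr <- mitofoci:::point_at_fraction(sec$boundary, nuc$arc_fraction[1])
  v <- sec$channels$dapi[round(ctr[2]) + 1, round(ctr[1]) + 1]
  expect_gt(v, 0.9 * (600 + 40))
})

test_that("focus arcs carry the prescribed SDHA fold and MTCOI attenuation", {
  p <- cohort_sim_params(
    n_fibers = 1, noise_sd = c(dapi = 0, sdha = 0, mtcoi = 0),
    background_level = c(dapi = 0, sdha = 0, mtcoi = 0),
    sdha_focus_fold = 3.3, mtcoi_focus_atten = 0.1, seed = 5)
  coh <- simulate_cohort(p)
  sec <- coh$sections[[1]]
  foc <- coh$truth$foci
  # probe a point a few px inside the boundary at the focus center
  rs <- mitofoci:::poly_resample(sec$boundary, 0.5)
  i <- which.min(mitofoci:::arc_distance(rs$frac, foc$center_frac))
  pt <- rs$points[i, ] + 4 * rs$normal[i, ]
  sdha <- sec$channels$sdha[round(pt[2]) + 1, round(pt[1]) + 1]
  mtcoi <- sec$channels$mtcoi[round(pt[2]) + 1, round(pt[1]) + 1]
  expect_equal(sdha, 330)   # 100 * 3.3, zero noise, before clipping
  expect_equal(mtcoi, 10)   # 100 * 0.1
  # outside the focus the baseline is untouched
  j <- which.max(mitofoci:::arc_distance(rs$frac, foc$center_frac))
  pt2 <- rs$points[j, ] + 4 * rs$normal[j, ]
  expect_equal(sec$channels$sdha[round(pt2[2]) + 1, round(pt2[1]) + 1], 100)
})

test_that("full enrichment places every focus interval on a nucleus", {
  coh <- simulate_cohort(cohort_sim_params(
    n_fibers = 30, enrichment_rho = 1, foci_per_fiber_prob = 1, seed = 8),
    render = FALSE)
  expect_equal(nrow(coh$truth$foci), 30)
  expect_true(all(coh$truth$foci$contains_nucleus))
})

test_that("without enrichment, focus centers are uniform on the perimeter", {
  # over >= 500 foci the fraction of centers landing in perinuclear arcs
  # approaches the mean perinuclear fraction within binomial error
  p <- cohort_sim_params(n_fibers = 500, enrichment_rho = 0, seed = 77)
  coh <- simulate_cohort(p, render = FALSE)
  ann <- annotate_from_truth(coh$truth, n_samples = 400,
                             halfwidth = p$perinuclear_halfwidth)
  hits <- mapply(function(fid, ctr) {
    m <- ann$perinuclear[ann$fiber_id == fid][[1]]
    m[(round(ctr * 400) %% 400) + 1]
  }, coh$truth$foci$fiber_id, coh$truth$foci$center_frac)
  p_mean <- mean(ann$P)
  se <- sqrt(p_mean * (1 - p_mean) / length(hits))
  expect_lt(abs(mean(hits) - p_mean), 4 * se)
})

test_that("simulated Cq follows the log-linear model exactly at zero noise", {
  truth <- tibble::tibble(fiber_id = "Q001", region_id = "Q001_focus",
                          region_kind = "focus",
                          dloop = 1, nd1 = 1024, nd4 = 512)
  plate <- simulate_qpcr_plate(truth, qpcr_sim_params(noise_sd = 0,
                                                      intercept = 40,
                                                      slope = -3.3219))
  smp <- plate[plate$region_kind == "focus", ]
  expect_equal(smp$cq[smp$target == "DLoop"], rep(40, 3))  # log10(1) = 0
  # 1024 = 2^10 copies: Cq drops by exactly 10 cycles
  expect_equal(unique(smp$cq[smp$target == "ND1"]), 40 - 10,
               tolerance = 1e-4)
  expect_equal(nrow(plate[plate$region_kind == "standard", ]),
               6 * 3 * 3)  # 6 dilutions x 3 targets x triplicate
  expect_true(all(c("NTC", "standard") %in% plate$region_kind))
})

test_that("zero true copies are reported as no amplification", {
  truth <- tibble::tibble(fiber_id = "Q001", region_id = "Q001_focus",
                          region_kind = "focus", dloop = 100, nd1 = 100,
                          nd4 = 0)
  plate <- simulate_qpcr_plate(truth, qpcr_sim_params(noise_sd = 0))
  expect_true(all(is.na(plate$cq[plate$region_kind == "focus" &
                                   plate$target == "ND4"])))
})

test_that("qPCR truth respects the deletion constraint nd4 <= nd1", {
  truth <- simulate_qpcr_truth(n_fibers = 10, seed = 4)
  expect_true(all(truth$nd4 <= truth$nd1 + 1e-12))
  expect_true(all(truth$dloop > 0 & truth$nd1 > 0))
  expect_identical(truth, simulate_qpcr_truth(n_fibers = 10, seed = 4))
})
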