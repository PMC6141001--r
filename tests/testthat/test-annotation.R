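test_that("cohort quantile threshold uses linear interpolation", {
  prof <- tibble::tibble(channel = "dapi", corrected = as.numeric(1:100))
  # sort-and-interpolate oracle: h = (n-1) q + 1 = 85.15 -> x85 + 0.15 * (x86 - x85)
  expect_equal(cohort_dapi_threshold(prof, 0.85), 85.15)
  # q -> 1 limit approaches the pooled maximum
  expect_equal(cohort_dapi_threshold(prof, 0.999999), 100, tolerance = 1e-3)
  # all values equal -> threshold is that value, strict '>' empties the mask
  prof2 <- tibble::tibble(channel = "dapi", corrected = rep(5, 50))
  thr <- cohort_dapi_threshold(prof2, 0.85)
  expect_equal(thr, 5)
  expect_false(any(annotate_perinuclear(prof2$corrected, thr)))
  expect_error(cohort_dapi_threshold(prof[0, ], 0.85), "no corrected DAPI")
  expect_error(
    cohort_dapi_threshold(tibble::tibble(channel = "dapi", corrected = 1:5),
                          0.85), "small")
})

test_that("perinuclear masks honour strict threshold, min_run and wraparound", {
  v <- c(9, 9, 1, 1, 1, 1, 1, 9, 9, 9)  # run crossing the seam: 8..2
  m <- annotate_perinuclear(v, 5, min_run = 3)
  expect_equal(which(m), c(1, 2, 8, 9, 10))
  expect_equal(nrow(cyclic_runs(m)), 1)  # one wrapped run, not two
  # short runs removed cyclically
  v2 <- c(9, 1, 1, 1, 1, 1, 1, 1, 1, 9)  # wrapped run of length 2
  expect_false(any(annotate_perinuclear(v2, 5, min_run = 3)))
  # ties excluded by the strict '>' rule
  expect_false(any(annotate_perinuclear(rep(5, 10), 5)))
})

test_that("zero-noise nuclei produce single perinuclear runs at truth", {
  coh <- zero_noise_cohort()
  prof <- profile_cohort(coh$sections)
  ann <- annotate_cohort(prof)
  expect_true(all(nuclei_recovered(ann, coh$truth$nuclei)))
  # a fiber with one nucleus yields exactly one contiguous run
  singles <- coh$truth$fibers$fiber_id[coh$truth$fibers$n_nuclei == 1]
  for (fid in singles) {
    m <- ann$perinuclear[ann$fiber_id == fid][[1]]
    expect_equal(nrow(cyclic_runs(m)), 1)
  }
})

test_that("automated deficiency rule finds foci and rejects uniform fibers", {
  # uniform channels -> no deficiency
  expect_false(any(classify_deficient_points(rep(10, 50), rep(10, 50))))
  expect_error(classify_deficient_points(rep(1, 10), rep(0, 10)), "SDHA")
  # synthetic focus (MTCOI x0.1, SDHA x3.3, zero noise): mask matches the
  # truth interval to within a couple of samples at each edge
  coh <- zero_noise_cohort()
  prof <- profile_cohort(coh$sections)
  ann <- annotate_cohort(prof)
  for (i in seq_len(nrow(ann))) {
    foc <- coh$truth$foci[coh$truth$foci$fiber_id == ann$fiber_id[i], ]
    n <- ann$n_samples[i]
    truth_mask <- mitofoci:::mask_from_intervals(foc$start_frac, foc$end_frac, n)
    detected <- ann$focal[[i]]
    mismatch <- sum(xor(truth_mask, detected))
    expect_lte(mismatch, 6)  # <= ~3 samples per focus edge
  }
})

test_that("manual annotations override the automated rule verbatim", {
  coh <- zero_noise_cohort()
  prof <- profile_cohort(coh$sections)
  manual <- tibble::tibble(fiber_id = "F001", start_frac = 0.9,
                           end_frac = 0.1)  # wraparound interval
  ann <- annotate_cohort(prof, manual = manual)
  m <- ann$focal[ann$fiber_id == "F001"][[1]]
  n <- length(m)
  expect_identical(m, mitofoci:::mask_from_intervals(0.9, 0.1, n))
  expect_true(m[1])            # mask true across the 0 seam
  expect_true(m[n])
  expect_false(m[round(n / 2)])
  # other fibers still use the automated rule
  expect_gt(ann$F[ann$fiber_id == "F002"], 0)
})

test_that("fiber classification follows coverage thresholds", {
  expect_equal(classify_fiber(1.0)$label, "COX-deficient")
  expect_false(classify_fiber(1.0)$has_focus)
  expect_equal(classify_fiber(0.2)$label, "COX-positive")
  expect_true(classify_fiber(0.2)$has_focus)
  expect_equal(classify_fiber(0)$label, "COX-positive")
  expect_false(classify_fiber(0)$has_focus)
  expect_equal(classify_fiber(0.7)$label, "intermediate")
  expect_equal(classify_fiber(0.96)$label, "COX-deficient")
})

test_that("prevalence summary reports counts, percentages and 1:x ratios", {
  classes <- dplyr::bind_rows(
    tibble::tibble(label = rep("COX-positive", 898), has_focus = FALSE),
    tibble::tibble(label = rep("COX-positive", 2), has_focus = TRUE),
    tibble::tibble(label = rep("COX-deficient", 100), has_focus = FALSE))
  s <- prevalence_summary(classes)
  expect_equal(s$n_fibers, 1000)
  expect_equal(s$pct_foci, 0.2)
  expect_equal(s$pct_fully_deficient, 10)
  expect_equal(s$foci_to_total, "1:500")
  expect_equal(s$foci_to_deficient, "1:50")
  # zero foci -> undefined ratios, not a division error
  s0 <- prevalence_summary(tibble::tibble(label = "COX-positive",
                                          has_focus = FALSE))
  expect_equal(s0$pct_foci, 0)
  expect_equal(s0$foci_to_total, "undefined")
  # degenerate single focus fiber
  s1 <- prevalence_summary(tibble::tibble(label = "COX-positive",
                                          has_focus = TRUE))
  expect_equal(s1$pct_foci, 100)
  expect_equal(s1$foci_to_total, "1:1")
})

test_that("raising the quantile monotonically shrinks P", {
  coh <- zero_noise_cohort()
  prof <- profile_cohort(coh$sections)
  Ps <- sapply(c(0.7, 0.85, 0.95), function(q) {
    ann <- annotate_cohort(prof, analysis_config(quantile_q = q))
    mean(ann$P)
  })
  expect_true(all(diff(Ps) <= 0))
})

test_that("mask identities hold for every annotation", {
  coh <- zero_noise_cohort()
  ann <- annotate_cohort(profile_cohort(coh$sections))
  for (i in seq_len(nrow(ann))) {
    peri <- ann$perinuclear[[i]]; foc <- ann$focal[[i]]
    expect_equal(ann$P[i], mean(peri))
    expect_equal(ann$F[i], mean(foc))
    expect_equal(ann$O_obs[i], mean(peri & foc))
    expect_lte(ann$O_obs[i], min(ann$P[i], ann$F[i]))
  }
})
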