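make_standards <- function(slope, intercept = 40, copies = 10^(7:2)) {
  tibble::tibble(copies = copies, cq = intercept + slope * log10(copies))
}

test_that("standard-curve fits recover slope, intercept and efficiency", {
  cv <- fit_standard_curve(make_standards(-3.3219), "ND1")
  expect_equal(cv$slope, -3.3219, tolerance = 1e-9)
  expect_equal(cv$intercept, 40, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$efficiency, 1, tolerance = 1e-4)  # doubling per cycle
  expect_true(cv$qc_pass)
  # slope -3.45 -> efficiency 10^(1/3.45) - 1 = 0.949, just under the gate
  cv2 <- fit_standard_curve(make_standards(-3.45), "ND1")
  expect_equal(cv2$efficiency, 10^(1 / 3.45) - 1, tolerance = 1e-9)
  expect_lt(cv2$efficiency, 0.95)
  expect_false(cv2$qc_pass)
  expect_error(fit_standard_curve(make_standards(3)), "slope")
  expect_error(fit_standard_curve(make_standards(-3.3)[1:3, ]), "4 distinct")
})

test_that("copy quantification inverts the curve and honours QC", {
  cv <- fit_standard_curve(make_standards(-3.3219), "ND1")
  expect_equal(quantify_copies(40, cv), 1, tolerance = 1e-9)
  expect_equal(quantify_copies(30, cv), 1024, tolerance = 1e-4)  # 2^10
  expect_equal(quantify_copies(NA_real_, cv), 0)  # no amplification
  bad <- fit_standard_curve(make_standards(-3.45), "ND1")
  expect_error(quantify_copies(30, bad), "QC")
  expect_gt(quantify_copies(30, bad, override = TRUE), 0)
})

test_that("deletion level follows the 0-100 ND4/ND1 scale with clipping", {
  expect_equal(deletion_level(1000, 1000), 0)
  expect_equal(deletion_level(1000, 0), 100)
  expect_equal(deletion_level(1000, 1200), 0)   # negative raw value clipped
  expect_equal(deletion_level(1000, 500), 50)
  expect_true(is.na(deletion_level(0, 10)))     # undefined, flagged upstream
  # scale invariance: multiplying both copies by c > 0 changes nothing
  expect_equal(deletion_level(3.7 * 1000, 3.7 * 400),
               deletion_level(1000, 400))
})

test_that("D-Loop/ND1 check flags only ND1-intact outliers", {
  expect_false(dloop_nd1_check(100, 100)$dloop_flag)
  expect_true(dloop_nd1_check(300, 100)$dloop_flag)
  expect_false(dloop_nd1_check(300, 100, nd1_intact = FALSE)$dloop_flag)
})

test_that("the NTC margin gates whole fiber groups", {
  cq <- tibble::tibble(fiber_id = c("A", "A", "B", "B"),
                       region_id = c("A_f", "A_p", "B_f", "B_p"),
                       nd1_cq = c(30, 30.5, 30, 32))
  out <- ntc_filter(cq, ntc_cq = 34, margin = 3)
  expect_true(out$ntc_pass[out$fiber_id == "A"])   # margins 4 and 3.5
  expect_false(out$ntc_pass[out$fiber_id == "B"])  # one region at margin 2
  # sentinel NTC (no amplification) passes any amplified region
  out2 <- ntc_filter(cq, ntc_cq = NA_real_, margin = 3)
  expect_true(all(out2$ntc_pass))
  # QC monotonicity: a larger margin never passes more groups
  n_pass <- sapply(c(1, 3, 4.5), function(m) {
    sum(ntc_filter(cq, 34, m)$ntc_pass)
  })
  expect_true(all(diff(n_pass) <= 0))
})

test_that("zero-noise plates round-trip copies and deletion exactly", {
  truth <- simulate_qpcr_truth(n_fibers = 6, seed = 19)
  plate <- simulate_qpcr_plate(truth, qpcr_sim_params(noise_sd = 0, seed = 19))
  q <- quantify_plate(plate)
  expect_true(all(sapply(q$curves, `[[`, "qc_pass")))
  reg <- dplyr::inner_join(q$regions, truth, by = "region_id")
  expect_lt(max(abs(reg$copies_nd1 - reg$nd1) / reg$nd1), 1e-6)
  expect_lt(max(abs(reg$copies_dloop - reg$dloop) / reg$dloop), 1e-6)
  expect_lt(max(abs(reg$copies_nd4 - reg$nd4) / pmax(reg$nd4, 1)), 1e-6)
  expect_lt(max(abs(reg$deletion_level -
                      (1 - reg$nd4 / reg$nd1) * 100), na.rm = TRUE), 1e-6)
  expect_true(all(reg$ntc_pass))
})

test_that("plate CSV round trip preserves the quantification", {
  truth <- simulate_qpcr_truth(n_fibers = 3, seed = 2)
  plate <- simulate_qpcr_plate(truth, qpcr_sim_params(noise_sd = 0, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(plate, path)
  plate2 <- read_plate_csv(path)
  q1 <- quantify_plate(plate)$regions
  q2 <- quantify_plate(plate2)$regions
  expect_equal(q2$copies_nd1, q1$copies_nd1, tolerance = 1e-12)
})

test_that("paired analysis recovers folds and handles edge cases", {
  truth <- simulate_qpcr_truth(n_fibers = 27, fold_sd = 0.25, seed = 101)
  plate <- simulate_qpcr_plate(truth, qpcr_sim_params(noise_sd = 0.05,
                                                      seed = 102))
  pa <- paired_region_analysis(quantify_plate(plate, override_qc = TRUE))
  g <- glance(pa)
  expect_equal(g$n_pairs, 27)
  expect_lt(abs(g$mean_dloop_fold - 2.2) / 2.2, 0.15)
  expect_lt(abs(g$mean_nd1_fold - 2.5) / 2.5, 0.15)
  expect_lt(g$p_dloop, 0.01)
  expect_gt(g$mean_deletion_diff, 20)
  expect_s3_class(autoplot(pa), "ggplot")
  expect_equal(nrow(pa$whole_fiber), 3)

  # identical pairs give t = 0 flagged degenerate; opposite differences too
  pt <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pt$statistic, 0)
  expect_equal(pt$p_value, 1)
  pt2 <- paired_t(c(2, 1), c(1, 2))  # differences +1, -1 -> t = 0, p = 1
  expect_equal(pt2$statistic, 0)
  expect_equal(pt2$p_value, 1)
})

test_that("an unmatched focus is excluded with a warning", {
  truth <- simulate_qpcr_truth(n_fibers = 3, fold_sd = 0, seed = 7)
  truth <- truth[truth$region_id != "Q002_pos1" &
                   truth$region_id != "Q002_pos2", ]
  plate <- simulate_qpcr_plate(truth, qpcr_sim_params(noise_sd = 0, seed = 7))
  # fold_sd = 0 makes the paired tests degenerate by design; the check here
  # is the exclusion behaviour
  suppressWarnings(expect_warning(
    pa <- paired_region_analysis(quantify_plate(plate)), "Q002"))
  expect_equal(nrow(pa$pairs), 2)
  expect_true("Q002" %in% pa$excluded)
})

test_that("a fiber group failing the NTC margin is excluded downstream", {
  truth <- simulate_qpcr_truth(n_fibers = 4, fold_sd = 0, seed = 3)
  # push one fiber's matched regions near the NTC: tiny copy numbers
  truth$nd1[truth$region_id %in% c("Q003_pos1", "Q003_pos2")] <- 5
  plate <- simulate_qpcr_plate(truth, qpcr_sim_params(noise_sd = 0, seed = 3,
                                                      ntc_cq = 40 - 3.3219 *
                                                        log10(5) + 2))
  q <- quantify_plate(plate)
  pa <- suppressWarnings(paired_region_analysis(q))  # fold_sd = 0: degenerate t
  expect_true("Q003" %in% pa$excluded)
  expect_false("Q003" %in% pa$pairs$fiber_id)
  expect_equal(nrow(pa$pairs), 3)
})
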