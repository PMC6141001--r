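test_that("modal background is the mode of unsaturated intensities", {
  expect_equal(estimate_modal_background(matrix(50, 10, 10)), 50)
  # most frequent value saturated -> mode of the remaining values
  r <- matrix(c(rep(65535, 60), rep(40, 30), rep(10, 10)), 10, 10)
  expect_equal(estimate_modal_background(r, 65535), 40)
  expect_error(estimate_modal_background(matrix(65535, 3, 3), 65535),
               "saturated")
  # on a generated raster the background mode survives sparse nuclei blobs
  coh <- zero_noise_cohort()
  bg <- estimate_modal_background(coh$sections[[1]]$channels$dapi)
  expect_lte(abs(bg - 40), 1)
})

test_that("background correction subtracts and floors at zero", {
  prof <- tibble::tibble(channel = c("dapi", "dapi", "sdha"),
                         raw = c(100, 30, 50))
  out <- correct_profile(prof, c(dapi = 40, sdha = 0))
  expect_equal(out$corrected, c(60, 0, 50))
  # idempotent once the post-correction mode is zero
  out2 <- correct_profile(dplyr::mutate(out, raw = corrected),
                          c(dapi = 0, sdha = 0))
  expect_equal(out2$corrected, out$corrected)
  expect_error(correct_profile(prof, c(dapi = 40)), "sdha")
})

test_that("perimeter profile sampling on a square fiber", {
  sec <- make_square_section(side = 100)
  prof <- extract_perimeter_profile(sec, step_px = 1, band_depth_px = 10)
  # 400 px perimeter sampled every 1 px -> 400 samples per channel
  expect_equal(nrow(prof), 400 * 3)
  expect_equal(attr(prof, "perimeter_px"), 400)
  # uniform raster -> constant profile at the raster value
  expect_true(all(abs(prof$raw[prof$channel == "sdha"] - 80) < 1e-9))
  d <- prof[prof$channel == "dapi", ]
  expect_true(all(diff(d$arc_fraction) > 0))
})

test_that("DAPI profile peaks at the true nucleus arc position", {
  coh <- zero_noise_cohort()
  sec <- coh$sections[[2]]
  prof <- extract_perimeter_profile(sec, 1, 10)
  d <- prof[prof$channel == "dapi", ]
  nuc <- coh$truth$nuclei[coh$truth$nuclei$fiber_id == sec$fiber_id, ]
  peak_frac <- d$arc_fraction[which.max(d$raw)]
  expect_lt(min(mitofoci:::arc_distance(peak_frac, nuc$arc_fraction)) *
              nrow(d), 2.5)
})

test_that("profiles are invariant to integer translation of image and polygon", {
  coh <- zero_noise_cohort()
  sec <- coh$sections[[1]]
  prof <- extract_perimeter_profile(sec, 2, 8)
  ch <- sec$channels
  shift <- function(m, dx, dy) {
    out <- matrix(mitofoci:::estimate_modal_background(m),
                  nrow(m) + dy, ncol(m) + dx)
    out[(dy + 1):(dy + nrow(m)), (dx + 1):(dx + ncol(m))] <- m
    out
  }
  sec2 <- sec
  sec2$boundary <- sec$boundary + matrix(rep(c(7, 5), each = nrow(sec$boundary)),
                                         ncol = 2)
  sec2$channels <- lapply(ch, shift, dx = 7, dy = 5)
  prof2 <- extract_perimeter_profile(sec2, 2, 8)
  expect_equal(prof2$raw, prof$raw, tolerance = 1e-9)
})

test_that("line scans interpolate bilinearly and rotate with the image", {
  sec <- make_square_section(side = 60)
  ls <- extract_line_scan(sec, c(30, 50), c(90, 50))
  expect_equal(nrow(ls), 61 * 3)  # ceil(60) + 1 samples per channel
  expect_true(all(ls$raw[ls$channel == "mtcoi"] == 80))
  # background subtraction floors at zero
  ls2 <- extract_line_scan(sec, c(30, 50), c(90, 50),
                           background = c(dapi = 60, sdha = 0, mtcoi = 0))
  expect_true(all(ls2$corrected[ls2$channel == "dapi"] == 0))
  expect_error(extract_line_scan(sec, c(-5, 0), c(10, 10)), "inside")

  # 90-degree rotation of image + endpoints preserves scan values
  coh <- zero_noise_cohort()
  fsec <- coh$sections[[1]]
  h <- nrow(fsec$channels$dapi)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]  # (x,y)->(h-1-y, x)
  rsec <- fsec
  rsec$channels <- lapply(fsec$channels, rot90)
  p1 <- c(40, 60); p2 <- c(120, 90)
  rp <- function(p) c(h - 1 - p[2], p[1])
  a <- extract_line_scan(fsec, p1, p2)
  b <- extract_line_scan(rsec, rp(p1), rp(p2))
  expect_equal(b$raw, a$raw, tolerance = 1e-9)
})

test_that("a focus reads as attenuated MTCOI on a transect", {
  p <- cohort_sim_params(n_fibers = 1,
                         noise_sd = c(dapi = 0, sdha = 0, mtcoi = 0),
                         background_level = c(dapi = 0, sdha = 0, mtcoi = 0),
                         seed = 21)
  coh <- simulate_cohort(p)
  sec <- coh$sections[[1]]
  foc <- coh$truth$foci
  rs <- mitofoci:::poly_resample(sec$boundary, 0.5)
  i <- which.min(mitofoci:::arc_distance(rs$frac, foc$center_frac))
  inside_pt <- rs$points[i, ] + 4 * rs$normal[i, ]
  center <- colMeans(sec$boundary)
  ls <- extract_line_scan(sec, inside_pt, center)
  m <- ls$raw[ls$channel == "mtcoi"]
  expect_lt(m[1], 15)                  # attenuated x0.1 inside the focus band
  expect_gt(m[length(m)], 90)          # baseline at the fiber center
})

test_that("profile band mean matches the raster band mean on uniform data", {
  sec <- make_square_section(side = 80, value = c(dapi = 7, sdha = 9,
                                                  mtcoi = 11))
  prof <- profile_cohort(list(sec),
                         analysis_config(sampling_step_px = 2,
                                         band_depth_px = 6))
  # modal background equals the constant, so corrected is exactly 0
  expect_true(all(prof$corrected == 0))
  expect_true(all(prof$raw[prof$channel == "mtcoi"] == 11))
})
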