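test_that("orientation is recovered for rotated and horizontal phantoms", {
  ph <- make_lengthwise_phantom(shape_px = c(512, 512), repeat_um = 3.2,
                                fibril_width_um = 1.0,
                                fibril_spacing_um = 2.0,
                                rotation_deg = 30, psf_sigma_um = 0.15,
                                photon_peak = 50, seed = 2)
  rs <- orient_and_tile(ph$image)
  expect_lt(abs(rs$rotation_deg - (-30)), 2)
  ph0 <- make_lengthwise_phantom(shape_px = c(256, 256), rotation_deg = 0,
                                 photon_peak = 50, seed = 3)
  rs0 <- orient_and_tile(ph0$image)
  expect_lt(abs(rs0$rotation_deg), 1)
  expect_equal(length(rs0$rois), 9L)
})

test_that("images too small for the ROI floor raise a size error", {
  set.seed(1)
  img <- image2d(matrix(runif(100 * 100), 100), 0.05)
  expect_error(orient_and_tile(img, rotate_deg = 0),
               class = "myofq_size_error")
})

test_that("sarcomere repeat is recovered across noise regimes", {
  # noiseless adult-stage striation
  ph <- make_lengthwise_phantom(shape_px = c(256, 512), repeat_um = 3.2,
                                fibril_width_um = 1.0,
                                fibril_spacing_um = 2.0,
                                psf_sigma_um = 0, photon_peak = Inf)
  expect_equal(estimate_repeat(ph$image)$repeat_um, 3.2, tolerance = 0.05 / 3.2)
  # pure cosine, integer period 40 px at 50 nm/px
  img <- image2d(outer(rep(1, 64), cos(2 * pi * (0:511) / 40)) + 2, 0.05)
  expect_equal(estimate_repeat(img)$repeat_um, 2.0, tolerance = 0.05 / 2.0)
  # Poisson shot noise at photon peak 50
  php <- make_lengthwise_phantom(shape_px = c(256, 512), repeat_um = 2.5,
                                 fibril_width_um = 0.8,
                                 fibril_spacing_um = 1.6,
                                 psf_sigma_um = 0.15, photon_peak = 50,
                                 seed = 5)
  expect_equal(estimate_repeat(php$image)$repeat_um, 2.5,
               tolerance = 0.05 / 2.5)
})

test_that("width equals the first vertical ACF minimum, exactly at 50% duty", {
  ph <- make_lengthwise_phantom(shape_px = c(256, 512), repeat_um = 2.0,
                                fibril_width_um = 0.5,
                                fibril_spacing_um = 1.0,
                                psf_sigma_um = 0, photon_peak = Inf)
  w <- estimate_width(ph$image)
  expect_true(w$minimum_found)
  expect_equal(w$width_um, 0.5, tolerance = 0.05 / 0.5)
})

test_that("a single fibril gives a monotone ACF and a no-minimum flag", {
  y <- (0:127) * 0.05
  prof <- exp(-(y - 3.2)^2 / (2 * 0.4^2))
  img <- image2d(outer(prof, rep(1, 256)) * 50 + 1, 0.05)
  w <- estimate_width(img)
  expect_false(w$minimum_found)
  expect_true(is.na(w$width_um))
})

test_that("the first-minimum width depends on duty cycle, exact only at 50%", {
  est <- vapply(c(0.3, 0.5, 0.7), function(duty) {
    ph <- make_lengthwise_phantom(shape_px = c(256, 512), repeat_um = 2.0,
                                  fibril_width_um = 0.5,
                                  fibril_spacing_um = 0.5 / duty,
                                  psf_sigma_um = 0, photon_peak = Inf)
    estimate_width(ph$image)$width_um
  }, numeric(1))
  expect_equal(est[2], 0.5, tolerance = 0.05 / 0.5)
  expect_gt(abs(est[1] - 0.5), 0.05)  # over-estimates at 30% duty
  expect_gt(abs(est[3] - 0.5), 0.05)  # under-estimates at 70% duty
})

test_that("full lengthwise analysis recovers stage parameters over 9 ROIs", {
  # adult stage: repeat 3.2 um
  ph <- make_lengthwise_phantom(shape_px = c(512, 1024), repeat_um = 3.2,
                                fibril_width_um = 1.0,
                                fibril_spacing_um = 2.0,
                                psf_sigma_um = 0.15, photon_peak = 50,
                                seed = 1)
  res <- analyze_lengthwise(ph$image)
  expect_equal(res$summary$mean[1], 3.2, tolerance = 0.05 / 3.2)
  expect_equal(res$n_roi_ok, 9L)
  # per-ROI consistency on a homogeneous phantom: CV < 2%
  reps <- res$per_roi$repeat_um
  expect_lt(stats::sd(reps) / mean(reps), 0.02)
  # early stage: repeat 2.0, width 0.5 recovered within 1 px equivalent
  ph9 <- make_lengthwise_phantom(shape_px = c(512, 1024), repeat_um = 2.0,
                                 fibril_width_um = 0.5,
                                 fibril_spacing_um = 1.0,
                                 psf_sigma_um = 0.15, photon_peak = 50,
                                 seed = 9)
  res9 <- analyze_lengthwise(ph9$image)
  expect_equal(res9$summary$mean[1], 2.0, tolerance = 0.05 / 2.0)
  expect_equal(res9$summary$mean[2], 0.5, tolerance = 0.05 / 0.5)
})

test_that("blank images raise a degenerate-input error", {
  img <- image2d(matrix(7, 256, 256), 0.05)
  expect_error(analyze_lengthwise(img), class = "myofq_degenerate_input")
})

test_that("repeat and width estimates are accurate and monotone across grids", {
  repeats <- seq(1.8, 3.4, by = 0.4)
  est_r <- vapply(repeats, function(r_um) {
    ph <- make_lengthwise_phantom(shape_px = c(256, 512), repeat_um = r_um,
                                  fibril_width_um = 0.8,
                                  fibril_spacing_um = 1.6,
                                  psf_sigma_um = 0.15, photon_peak = 50,
                                  seed = 21)
    estimate_repeat(ph$image)$repeat_um
  }, numeric(1))
  expect_true(all(abs(est_r - repeats) <= 0.05))
  expect_true(all(diff(est_r) > 0))
  widths <- c(0.4, 0.75, 1.1, 1.5)
  est_w <- vapply(widths, function(w_um) {
    ph <- make_lengthwise_phantom(shape_px = c(384, 512), repeat_um = 2.4,
                                  fibril_width_um = w_um,
                                  fibril_spacing_um = 2 * w_um,
                                  psf_sigma_um = 0.15, photon_peak = 50,
                                  seed = 22)
    estimate_width(ph$image)$width_um
  }, numeric(1))
  expect_true(all(abs(est_w - widths) <= 0.05))
  expect_true(all(diff(est_w) > 0))
})

test_that("intensity rescaling does not change lengthwise estimates", {
  ph <- make_lengthwise_phantom(shape_px = c(256, 512), repeat_um = 2.6,
                                fibril_width_um = 0.8,
                                fibril_spacing_um = 1.6,
                                psf_sigma_um = 0.15, photon_peak = 50,
                                seed = 12)
  img2 <- image2d(2.5 * ph$image$pixels + 30, 0.05)
  expect_equal(estimate_repeat(img2)$repeat_um,
               estimate_repeat(ph$image)$repeat_um, tolerance = 1e-9)
  expect_equal(estimate_width(img2)$width_um,
               estimate_width(ph$image)$width_um, tolerance = 1e-9)
})
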