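test_that("initial diameter brackets the disk size on a hexagonal lattice", {
  px <- 0.05; nr <- 512
  sp <- 2.0 / px; r0 <- 0.5 / px
  centers <- NULL
  for (row in 0:12) for (col in 0:12) {
    cy <- 40 + row * sp * sqrt(3) / 2
    cx <- 40 + col * sp + (row %% 2) * sp / 2
    if (cy < nr - 40 && cx < nr - 40) centers <- rbind(centers, c(cy, cx))
  }
  img <- image2d(render_disks(nr, nr, centers, r0), px)
  d0 <- initial_diameter(img)
  expect_false(d0$fallback)
  expect_gte(d0$d0_um, 0.8)
  expect_lte(d0$d0_um, 1.4)
  # 90-degree rotation leaves the radial-average estimate unchanged
  d0r <- initial_diameter(image2d(rot90(img$pixels), px))
  expect_equal(d0$d0_um, d0r$d0_um, tolerance = 1e-9)
})

test_that("a single disk has a monotone radial ACF and triggers the fallback", {
  img <- image2d(render_disks(256, 256, cbind(128, 128), 40), 0.05)
  d0 <- initial_diameter(img)
  expect_true(d0$fallback)
  expect_equal(d0$d0_um, 1.0)
})

test_that("all planted cross-sections are detected at their planted positions", {
  ph <- make_crosswise_phantom(shape_px = c(1024, 1024),
                               disk_diameter_um = 1.0, n_disks = 100L,
                               min_separation_um = 3.0,
                               psf_sigma_um = 0.10, photon_peak = 50,
                               seed = 6)
  d0 <- initial_diameter(ph$image)
  set <- detect_cross_sections(ph$image, d0$d0_um)
  expect_equal(nrow(set$centers), 100L)
  # every detected centre within 1 px of a planted centre
  dmin <- vapply(seq_len(nrow(set$centers)), function(i) {
    sqrt(min((ph$centers[, 1] - set$centers[i, 1])^2 +
             (ph$centers[, 2] - set$centers[i, 2])^2))
  }, numeric(1))
  expect_true(all(dmin <= 1 + 1e-9))
})

test_that("blank fields raise empty-set / degenerate errors", {
  blank <- image2d(matrix(5, 256, 256), 0.05)
  expect_error(detect_cross_sections(blank, 1.0),
               class = "myofq_empty_set")
  expect_error(analyze_crosswise(blank), class = "myofq_degenerate_input")
})

test_that("of two peaks closer than the minimum separation, the brighter wins", {
  nr <- 128
  ys <- matrix(seq_len(nr), nr, nr); xs <- t(ys)
  blob <- function(cy, cx, amp)
    amp * exp(-((ys - cy)^2 + (xs - cx)^2) / (2 * 3^2))
  img <- image2d(blob(60, 60, 100) + blob(60, 68, 70) + 5, 0.05)
  set <- detect_cross_sections(img, d0_um = 1.0)  # min sep 0.8 um = 16 px
  expect_equal(nrow(set$centers), 1L)
  expect_equal(set$centers[1, ], c(59, 59), tolerance = 1.5)
})

test_that("averaging identical noiseless sections reproduces one section", {
  centers <- rbind(c(64, 64), c(64, 160), c(160, 64), c(160, 160))
  img <- image2d(render_disks(224, 224, centers, 10), 0.05)
  set <- structure(list(centers = centers - 1, crop_halfwidth_px = 20L,
                        valid_area_um2 = 100, d0_um = 1.0,
                        threshold = 0, pixel_size_um = 0.05),
                   class = "cross_section_set")
  tpl <- suppressWarnings(average_cross_section(img, set))
  one <- img$pixels[44:84, 44:84]
  expect_equal(tpl$pixels, one, tolerance = 1e-12)
  # single crop: template equals that crop
  set1 <- structure(list(centers = centers[1, , drop = FALSE] - 1,
                         crop_halfwidth_px = 20L, valid_area_um2 = 100,
                         d0_um = 1.0, threshold = 0, pixel_size_um = 0.05),
                    class = "cross_section_set")
  tpl1 <- suppressWarnings(average_cross_section(img, set1))
  expect_equal(tpl1$pixels, one, tolerance = 1e-12)
})

test_that("template averaging reduces residual noise like 1/sqrt(N)", {
  # identical disks on a grid, Poisson noise; template error vs the
  # noiseless field must shrink ~ sqrt(N2/N1)
  px <- 0.05
  rms_for <- function(n_side, seed) {
    step <- 56; h <- 14L
    centers <- as.matrix(expand.grid(
      y = step * (1:n_side) + 4, x = step * (1:n_side) + 4))
    nr <- step * (n_side + 1) + 8
    ideal <- render_disks(nr, nr, centers, 8, amplitude = 20,
                          background = 2)
    set.seed(seed)
    noisy <- matrix(rpois(nr * nr, ideal), nr, nr) * 1.0
    set <- structure(list(centers = centers - 1, crop_halfwidth_px = h,
                          valid_area_um2 = 1, d0_um = 16 * px,
                          threshold = 0, pixel_size_um = px),
                     class = "cross_section_set")
    tpl <- suppressWarnings(
      average_cross_section(image2d(noisy, px), set))
    ref <- ideal[(centers[1, 1] - h):(centers[1, 1] + h),
                 (centers[1, 2] - h):(centers[1, 2] + h)]
    sqrt(mean((tpl$pixels - ref)^2))
  }
  r4 <- mean(vapply(1:3, function(s) rms_for(2, s), numeric(1)))    # N = 4
  r36 <- mean(vapply(1:3, function(s) rms_for(6, s), numeric(1)))   # N = 36
  expect_equal(r4 / r36, 3, tolerance = 0.45)  # sqrt(36/4) = 3
})

test_that("template diameter matches oracle and nominal width on clean disks", {
  # noiseless binary disk, diameter 20 px at 50 nm/px -> 1.00 um
  img <- image2d(render_disks(128, 128, cbind(65, 65), 10,
                              amplitude = 1, background = 0), 0.05)
  tpl <- image2d(img$pixels[35:95, 35:95], 0.05)
  d <- diameter_from_template(tpl)
  # bin-centre discretization allows roughly half-a-bin slack at the edge
  expect_equal(d$diameter_um, 1.0, tolerance = 0.04 / 1.0)
  # Gaussian-blurred disk: equality with the dense-interpolation oracle
  blurred <- pmax(myofq:::gaussian_blur_fft(img$pixels, 2), 0)
  tplb <- image2d(blurred[35:95, 35:95], 0.05)
  db <- diameter_from_template(tplb)
  orc <- oracle_fw_fraction(db$radial_profile$axis,
                            db$radial_profile$values)
  expect_equal(db$diameter_um, orc, tolerance = 0.01 / db$diameter_um)
})

test_that("degenerate templates raise errors", {
  flat <- image2d(matrix(3, 33, 33), 0.05)
  expect_error(diameter_from_template(flat),
               class = "myofq_degenerate_template")
  # profile rising outward never crosses downward
  n <- 33; ctr <- 17
  ramp <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  expect_error(diameter_from_template(image2d(ramp, 0.05)),
               class = "myofq_no_crossing")
})

test_that("crosswise pipeline counts exactly and measures a density", {
  ph <- make_crosswise_phantom(shape_px = c(1024, 1024),
                               disk_diameter_um = 0.46, n_disks = 200L,
                               psf_sigma_um = 0.10, photon_peak = 50,
                               seed = 2)
  res <- analyze_crosswise(ph$image)
  expect_equal(res$n_detected, 200L)
  # density agrees with the planted density over the placement area
  margin_px <- ph$truth$border_margin_um / 0.05
  planted_area <- ((1024 - 1 - 2 * margin_px) * 0.05)^2
  expect_equal(res$density_per_um2, 200 / planted_area, tolerance = 0.05)
  expect_gt(res$diameter_um, 0)
})

test_that("diameter estimates are monotone in the true diameter", {
  est <- vapply(c(0.6, 1.0, 1.4), function(d_um) {
    ph <- make_crosswise_phantom(shape_px = c(1024, 1024),
                                 disk_diameter_um = d_um, n_disks = 60L,
                                 psf_sigma_um = 0.10, photon_peak = 50,
                                 seed = 13)
    analyze_crosswise(ph$image)$diameter_um
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("sharp-optics diameters are recovered within one pixel", {
  # with negligible blur the 26%-of-range width is the true diameter
  for (d_um in c(0.6, 1.0, 1.4)) {
    ph <- make_crosswise_phantom(shape_px = c(1024, 1024),
                                 disk_diameter_um = d_um, n_disks = 60L,
                                 psf_sigma_um = 0.02, photon_peak = 50,
                                 seed = 14)
    res <- analyze_crosswise(ph$image)
    expect_equal(res$diameter_um, d_um, tolerance = 0.05 / d_um)
    expect_equal(res$n_detected, 60L)
  }
})

test_that("optical blur widens the 26%-range readout by ~1.29 sigma", {
  # documented estimator property: measured ~ true + 2 * qnorm(0.74) * sigma
  sigma <- 0.10
  ph <- make_crosswise_phantom(shape_px = c(1024, 1024),
                               disk_diameter_um = 1.0, n_disks = 60L,
                               psf_sigma_um = sigma, photon_peak = 50,
                               seed = 15)
  res <- analyze_crosswise(ph$image)
  expected_bias <- 2 * qnorm(0.74) * sigma
  expect_equal(res$diameter_um - 1.0, expected_bias, tolerance = 0.35)
})

test_that("crosswise results are invariant under 90-degree rotation", {
  ph <- make_crosswise_phantom(shape_px = c(512, 512),
                               disk_diameter_um = 1.0, n_disks = 25L,
                               psf_sigma_um = 0.10, photon_peak = 50,
                               seed = 4)
  r1 <- analyze_crosswise(ph$image)
  r2 <- analyze_crosswise(image2d(rot90(ph$image$pixels), 0.05))
  expect_equal(r1$n_detected, r2$n_detected)
  expect_equal(r1$diameter_um, r2$diameter_um, tolerance = 1e-9)
  expect_equal(r1$d0_um, r2$d0_um, tolerance = 1e-9)
})

test_that("crosswise outputs are invariant to affine intensity rescaling", {
  ph <- make_crosswise_phantom(shape_px = c(512, 512),
                               disk_diameter_um = 1.0, n_disks = 25L,
                               psf_sigma_um = 0.10, photon_peak = 50,
                               seed = 5)
  r1 <- analyze_crosswise(ph$image)
  r2 <- analyze_crosswise(image2d(4 * ph$image$pixels + 11, 0.05))
  expect_equal(r1$n_detected, r2$n_detected)
  expect_equal(r1$diameter_um, r2$diameter_um, tolerance = 1e-9)
})
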