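#' Synthetic longitudinal (lengthwise) muscle phantom
#'
#' Renders parallel fibrils running along x: a periodic cross-fibril stripe
#' pattern (fibril body of width `fibril_width_um`, repeating every
#' `fibril_spacing_um`) carrying bright Z-lines every `repeat_um` along the
#' fibril axis, optionally rotated, blurred with a Gaussian PSF, scaled to
#' `photon_peak` expected photons, offset by a constant `background` and
#' Poisson-sampled. Emulates a phalloidin/Z-disc composite of fibrillar
#' flight muscle at confocal resolution without claiming optical realism.
#'
#' Defaults reflect the imaging convention of the measurements the package
#' reproduces: 50 nm pixels, a ~0.15 um PSF (roughly a high-NA confocal at
#' this sampling), Poisson shot noise with a peak of ~50 expected photons
#' and a small constant background.
#'
#' @param shape_px integer length-2, (rows, cols).
#' @param pixel_size_um micrometres per pixel (default 0.05).
#' @param repeat_um sarcomere repeat along the fibril axis; must exceed
#'   `2 * pixel_size_um` (Nyquist).
#' @param fibril_width_um width of the bright fibril body.
#' @param fibril_spacing_um centre-to-centre fibril spacing (>= width); the
#'   duty cycle is `fibril_width_um / fibril_spacing_um`.
#' @param profile cross-fibril body profile: `"rect"` (top-hat) or
#'   `"gaussian"` (FWHM = `fibril_width_um`).
#' @param zdisc_contrast in \[0, 1\]: 0 renders a plain body, 1 renders
#'   Z-lines at full scale on a dark body.
#' @param zline_px Z-line thickness in pixels (default 2).
#' @param rotation_deg fibril orientation; 0 = horizontal.
#' @param psf_sigma_um Gaussian PSF sigma (0 disables blurring).
#' @param photon_peak expected photon count at the brightest structure
#'   (> 0); `Inf` disables Poisson sampling (noiseless phantom).
#' @param background constant expected background photons.
#' @param seed integer RNG seed; regeneration with the same spec is
#'   bit-identical.
#' @return List with `image` ([image2d]) and `truth` (the full parameter
#'   record, sufficient to re-render the phantom exactly).
#' @export
make_lengthwise_phantom <- function(shape_px = c(512L, 1024L),
                                    pixel_size_um = 0.05,
                                    repeat_um = 3.2,
                                    fibril_width_um = 1.0,
                                    fibril_spacing_um = 2 * fibril_width_um,
                                    profile = c("rect", "gaussian"),
                                    zdisc_contrast = 0.6,
                                    zline_px = 2L,
                                    rotation_deg = 0,
                                    psf_sigma_um = 0.15,
                                    photon_peak = 50,
                                    background = 5,
                                    seed = 1L) {
  profile <- match.arg(profile)
  if (repeat_um <= 2 * pixel_size_um)
    myofq_stop("`repeat_um` must exceed two pixel sizes (Nyquist)",
               "myofq_spec_error")
  if (fibril_spacing_um < fibril_width_um)
    myofq_stop("`fibril_spacing_um` must be >= `fibril_width_um`",
               "myofq_spec_error")
  if (photon_peak <= 0)
    myofq_stop("`photon_peak` must be positive", "myofq_spec_error")
  nr <- as.integer(shape_px[1]); nc <- as.integer(shape_px[2])
  th <- rotation_deg * pi / 180
  # geometry in pixel units so that integer-pixel periods render exactly
  x <- rep(0:(nc - 1L), each = nr)
  y <- rep(0:(nr - 1L), times = nc)
  u <- x * cos(th) + y * sin(th)   # along fibril
  v <- -x * sin(th) + y * cos(th)  # across fibrils
  spacing_px <- fibril_spacing_um / pixel_size_um
  width_px <- fibril_width_um / pixel_size_um
  repeat_px <- repeat_um / pixel_size_um
  pv <- ((v %% spacing_px) + spacing_px) %% spacing_px
  body <- if (profile == "rect") {
    as.numeric(pv < width_px)
  } else {
    s <- width_px / (2 * sqrt(2 * log(2)))
    exp(-(pv - width_px / 2)^2 / (2 * s^2))
  }
  pu <- ((u %% repeat_px) + repeat_px) %% repeat_px
  zline <- as.numeric(pu < zline_px)
  ideal <- matrix(body * ((1 - zdisc_contrast) + zdisc_contrast * zline),
                  nr, nc)
  sig_px <- psf_sigma_um / pixel_size_um
  ideal <- gaussian_blur_fft(ideal, sig_px)
  if (is.finite(photon_peak)) {
    lambda <- background + photon_peak * pmax(ideal, 0)
    px <- with_seed(seed,
      matrix(stats::rpois(nr * nc, lambda), nr, nc))
    px <- px * 1.0
  } else {
    px <- background + pmax(ideal, 0)
  }
  truth <- list(class = "lengthwise", shape_px = c(nr, nc),
                pixel_size_um = pixel_size_um, repeat_um = repeat_um,
                fibril_width_um = fibril_width_um,
                fibril_spacing_um = fibril_spacing_um, profile = profile,
                zdisc_contrast = zdisc_contrast, zline_px = zline_px,
                rotation_deg = rotation_deg, psf_sigma_um = psf_sigma_um,
                photon_peak = photon_peak, background = background,
                seed = seed)
  list(image = image2d(px, pixel_size_um, label = "lengthwise_phantom"),
       truth = truth)
}

#' Synthetic transverse (crosswise) muscle phantom
#'
#' Places `n_disks` non-overlapping bright disks (myofibril cross-sections)
#' by dart throwing with a minimum centre separation, renders them with a
#' top-hat or Gaussian-edged profile, blurs with a Gaussian PSF and applies
#' Poisson shot noise over a constant background. Centres are kept at least
#' `border_margin_um` away from the frame so that every planted disk stays
#' measurable after the analysis discards border peaks.
#'
#' The top-hat edge (default) is the reference rendering: it is the only
#' profile for which the ground-truth diameter is unambiguous, which is what
#' a recovery test needs.
#'
#' @param shape_px integer length-2, (rows, cols).
#' @param pixel_size_um micrometres per pixel.
#' @param disk_diameter_um true disk diameter (> 2 pixels).
#' @param n_disks number of disks to place.
#' @param min_separation_um minimum centre-to-centre distance (default
#'   3 x diameter).
#' @param border_margin_um minimum centre distance from any frame edge
#'   (default 2 x diameter).
#' @param edge `"tophat"` or `"gaussian"` (disk with a soft edge of sigma =
#'   diameter/8 outside the nominal radius).
#' @param psf_sigma_um,photon_peak,background,seed as in
#'   [make_lengthwise_phantom()].
#' @param max_attempts dart-throwing attempt budget.
#' @return List with `image` ([image2d]), `centers` (n x 2 matrix of
#'   0-based (row, col) pixel coordinates) and `truth`.
#' @export
make_crosswise_phantom <- function(shape_px = c(1024L, 1024L),
                                   pixel_size_um = 0.05,
                                   disk_diameter_um = 1.0,
                                   n_disks = 100L,
                                   min_separation_um = 3 * disk_diameter_um,
                                   border_margin_um = 2 * disk_diameter_um,
                                   edge = c("tophat", "gaussian"),
                                   psf_sigma_um = 0.10,
                                   photon_peak = 50,
                                   background = 5,
                                   seed = 1L,
                                   max_attempts = 400000L) {
  edge <- match.arg(edge)
  nr <- as.integer(shape_px[1]); nc <- as.integer(shape_px[2])
  if (disk_diameter_um <= 2 * pixel_size_um)
    myofq_stop("`disk_diameter_um` must exceed two pixel sizes",
               "myofq_spec_error")
  if (photon_peak <= 0)
    myofq_stop("`photon_peak` must be positive", "myofq_spec_error")
  sep_px <- min_separation_um / pixel_size_um
  margin_px <- border_margin_um / pixel_size_um
  # feasibility guard: hard disks of radius sep/2 must fit loosely
  pack <- n_disks * pi * (sep_px / 2)^2 / (nr * nc)
  if (pack >= 0.6)
    myofq_stop(sprintf(
      "placement infeasible: exclusion packing fraction %.2f >= 0.6", pack),
      "myofq_placement_error")
  centers <- with_seed(seed, {
    acc <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(acc) < n_disks && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- c(stats::runif(1, margin_px, nr - 1 - margin_px),
                stats::runif(1, margin_px, nc - 1 - margin_px))
      if (nrow(acc) == 0L ||
          all((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2 >= sep_px^2))
        acc <- rbind(acc, cand)
    }
    acc
  })
  if (nrow(centers) < n_disks)
    myofq_stop(sprintf(
      "could not place %d disks after %d attempts (placed %d)",
      n_disks, max_attempts, nrow(centers)), "myofq_placement_error")
  dimnames(centers) <- NULL
  r_px <- disk_diameter_um / 2 / pixel_size_um
  ideal <- matrix(0, nr, nc)
  half <- ceiling(r_px + (if (edge == "gaussian") 4 * r_px / 4 else 2))
  for (i in seq_len(n_disks)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    rows <- max(0, floor(cy - half)):min(nr - 1, ceiling(cy + half))
    cols <- max(0, floor(cx - half)):min(nc - 1, ceiling(cx + half))
    d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
    patch <- if (edge == "tophat") {
      as.numeric(d <= r_px)
    } else {
      s <- r_px / 4
      ifelse(d <= r_px, 1, exp(-(d - r_px)^2 / (2 * s^2)))
    }
    ideal[rows + 1L, cols + 1L] <-
      pmax(ideal[rows + 1L, cols + 1L], patch)
  }
  ideal <- gaussian_blur_fft(ideal, psf_sigma_um / pixel_size_um)
  if (is.finite(photon_peak)) {
    lambda <- background + photon_peak * pmax(ideal, 0)
    px <- with_seed(seed + 1L,
      matrix(stats::rpois(nr * nc, lambda), nr, nc)) * 1.0
  } else {
    px <- background + pmax(ideal, 0)
  }
  truth <- list(class = "crosswise", shape_px = c(nr, nc),
                pixel_size_um = pixel_size_um,
                disk_diameter_um = disk_diameter_um, n_disks = n_disks,
                min_separation_um = min_separation_um,
                border_margin_um = border_margin_um, edge = edge,
                psf_sigma_um = psf_sigma_um, photon_peak = photon_peak,
                background = background, seed = seed)
  list(image = image2d(px, pixel_size_um, label = "crosswise_phantom"),
       centers = centers, truth = truth)
}

#' Default developmental stage table
#'
#' Ground-truth morphology per stage used by [make_stage_series()]:
#' sarcomere repeat and myofibril width stay near 2.0 and 0.5 um through
#' mid-pupal development, the cross-section diameter grows from 0.46 um to
#' 1.43 um by adulthood, and adult muscle with late spalt knock-down
#' reaches only a 2.8 um repeat.
#'
#' @return data.frame with columns `stage`, `repeat_um`, `width_um`,
#'   `diameter_um`.
#' @export
stage_table <- function() {
  data.frame(
    stage = c("30h_APF", "48h_APF", "adult", "salmIR_adult"),
    repeat_um = c(2.0, 2.0, 3.2, 2.8),
    width_um = c(0.5, 0.5, 1.43, 1.43),
    diameter_um = c(0.46, 0.46, 1.43, NA),
    stringsAsFactors = FALSE)
}

#' Phantom series across developmental stages
#'
#' Generates one lengthwise and (where a diameter is given) one crosswise
#' phantom per row of a stage table, with the table's values as ground
#' truth.
#'
#' @param table data.frame like [stage_table()]; that table is the default.
#' @param shape_lengthwise,shape_crosswise phantom shapes in pixels.
#' @param n_disks disks per crosswise phantom.
#' @param photon_peak,psf_sigma_um,pixel_size_um shared rendering
#'   parameters (see the phantom constructors).
#' @param seed base seed; row `i` uses `seed + i` (lengthwise) and
#'   `seed + 100 + i` (crosswise).
#' @return Named list (by stage) of lists with elements `lengthwise` and
#'   possibly `crosswise`, each as returned by the phantom constructors.
#' @export
make_stage_series <- function(table = stage_table(),
                              shape_lengthwise = c(512L, 1024L),
                              shape_crosswise = c(1024L, 1024L),
                              n_disks = 100L,
                              photon_peak = 50,
                              psf_sigma_um = 0.15,
                              pixel_size_um = 0.05,
                              seed = 1L) {
  need <- c("stage", "repeat_um", "width_um")
  if (!all(need %in% names(table)))
    myofq_stop("stage table needs columns stage, repeat_um, width_um",
               "myofq_spec_error")
  out <- list()
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    entry <- list(
      lengthwise = make_lengthwise_phantom(
        shape_px = shape_lengthwise, pixel_size_um = pixel_size_um,
        repeat_um = row$repeat_um, fibril_width_um = row$width_um,
        fibril_spacing_um = 2 * row$width_um,
        psf_sigma_um = psf_sigma_um, photon_peak = photon_peak,
        seed = seed + i))
    if (!is.null(table$diameter_um) && is.finite(row$diameter_um)) {
      entry$crosswise <- make_crosswise_phantom(
        shape_px = shape_crosswise, pixel_size_um = pixel_size_um,
        disk_diameter_um = row$diameter_um, n_disks = n_disks,
        psf_sigma_um = min(psf_sigma_um, 0.10), photon_peak = photon_peak,
        seed = seed + 100L + i)
    }
    out[[row$stage]] <- entry
  }
  out
}
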