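#' Orient fibrils horizontally and tile into ROIs
#'
#' Estimates the dominant fibril direction from the 2-D power spectrum: the
#' principal axis of the second-moment tensor of in-band spectral power
#' gives the direction of strongest periodic variation, which for elongated
#' fibrils is perpendicular to the fibril axis (the inter-fibril spacing
#' carries far more power than the along-fibril striation). The image is
#' rotated (bilinear interpolation) so fibrils run horizontally, and the
#' central part of the largest fully-valid rectangle is tiled into a grid
#' of non-overlapping rectangular ROIs — nine by default.
#'
#' @param img an [image2d].
#' @param grid integer length-2, ROI grid (rows, cols); default `c(3, 3)`.
#' @param rotate_deg manual override: when given, no orientation is
#'   estimated and this rotation is applied directly.
#' @param band_um period band (um) whose frequencies enter the orientation
#'   tensor; default `c(0.3, 10)`.
#' @param min_roi_px minimum ROI side in pixels (default 64).
#' @param central_frac fraction of the valid rectangle that is tiled
#'   (default 0.9).
#' @return An object of class `roiset`: list with `rois` (list of
#'   [image2d]), `rotation_deg`, `grid`, `isotropic` (flag: no dominant
#'   direction found, rotation left at 0), `parent_dim`.
#' @export
orient_and_tile <- function(img, grid = c(3L, 3L), rotate_deg = NULL,
                            band_um = c(0.3, 10), min_roi_px = 64L,
                            central_frac = 0.9) {
  assert_image2d(img)
  grid <- as.integer(grid)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  isotropic <- FALSE
  if (is.null(rotate_deg)) {
    est <- estimate_orientation(img, band_um)
    rotate_deg <- est$rotation_deg
    isotropic <- est$isotropic
  }
  rot <- if (rotate_deg %% 360 == 0) img$pixels
         else rotate_bilinear(img$pixels, rotate_deg)
  # largest centred axis-aligned rectangle free of out-of-frame samples
  th <- abs(rotate_deg %% 180) * pi / 180
  if (th > pi / 2) th <- pi - th
  ct <- abs(cos(th)); st <- abs(sin(th))
  s <- min((nc / 2) / ((nc / 2) * ct + (nr / 2) * st),
           (nr / 2) / ((nc / 2) * st + (nr / 2) * ct), 1)
  hh <- floor(nr / 2 * s * central_frac)
  hw <- floor(nc / 2 * s * central_frac)
  cy <- center_index(nr); cx <- center_index(nc)
  sub <- rot[(cy - hh):(cy + hh - 1L), (cx - hw):(cx + hw - 1L),
             drop = FALSE]
  tr <- nrow(sub) %/% grid[1]; tc <- ncol(sub) %/% grid[2]
  if (tr < min_roi_px || tc < min_roi_px)
    myofq_stop(sprintf(
      "image too small: %d x %d px tiles fall below the %d px ROI floor",
      tr, tc, min_roi_px), "myofq_size_error")
  rois <- list()
  for (i in seq_len(grid[1])) {
    for (j in seq_len(grid[2])) {
      tile <- sub[((i - 1L) * tr + 1L):(i * tr),
                  ((j - 1L) * tc + 1L):(j * tc), drop = FALSE]
      if (anyNA(tile)) tile[is.na(tile)] <- stats::median(tile, na.rm = TRUE)
      rois[[length(rois) + 1L]] <-
        image2d(pmax(tile, 0), img$pixel_size_um,
                label = sprintf("roi_%d_%d", i, j))
    }
  }
  structure(list(rois = rois, rotation_deg = rotate_deg, grid = grid,
                 isotropic = isotropic, parent_dim = c(nr, nc),
                 pixel_size_um = img$pixel_size_um),
            class = "roiset")
}

# Principal direction of in-band spectral power. Returns the rotation (deg)
# that brings the fibril axis horizontal, i.e. minus the fibril angle.
estimate_orientation <- function(img, band_um = c(0.3, 10)) {
  x <- img$pixels - mean(img$pixels)
  nr <- nrow(x); nc <- ncol(x)
  P <- Mod(stats::fft(x))^2
  P <- P[fftshift_index(nr), fftshift_index(nc)]
  fy <- (seq_len(nr) - center_index(nr)) / (nr * img$pixel_size_um)
  fx <- (seq_len(nc) - center_index(nc)) / (nc * img$pixel_size_um)
  FY <- matrix(fy, nr, nc); FX <- matrix(fx, nr, nc, byrow = TRUE)
  fr <- sqrt(FX^2 + FY^2)
  w <- P * (fr >= 1 / band_um[2] & fr <= 1 / band_um[1])
  sw <- sum(w)
  if (sw == 0) return(list(rotation_deg = 0, isotropic = TRUE))
  mxx <- sum(w * FX^2) / sw
  myy <- sum(w * FY^2) / sw
  mxy <- sum(w * FX * FY) / sw
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
  if (ev$values[1] < 1.2 * ev$values[2])
    return(list(rotation_deg = 0, isotropic = TRUE))
  # angle of the dominant spectral direction, y measured downwards
  theta_p <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  fibril <- theta_p + 90
  fibril <- ((fibril + 90) %% 180) - 90  # normalise to (-90, 90]
  list(rotation_deg = -fibril, isotropic = FALSE)
}

#' Sarcomere repeat from the horizontal Fourier peak
#'
#' The repeat is the reciprocal of the dominant peak on the horizontal
#' frequency axis of the image's power spectrum, searched inside a period
#' band. The spectrum is Hann-windowed and 4x zero-padded so the parabolic
#' log-power interpolation resolves the peak well below one original
#' frequency bin.
#'
#' @param roi an [image2d] with fibrils horizontal.
#' @param band_um period search band in micrometres, default `c(1, 5)`
#'   (brackets all reported sarcomere lengths while excluding DC and
#'   single-pixel regimes).
#' @param pad_factor zero-padding factor passed to
#'   [horizontal_power_spectrum()].
#' @return List with `repeat_um`, `prominence`, `at_edge`.
#' @export
estimate_repeat <- function(roi, band_um = c(1, 5), pad_factor = 4L) {
  assert_image2d(roi)
  if (length(band_um) != 2L || band_um[1] <= 0 || band_um[1] >= band_um[2])
    myofq_stop("`band_um` must be c(min_period, max_period), 0 < min < max",
               "myofq_band_error")
  sp <- horizontal_power_spectrum(roi, window = "hann",
                                  pad_factor = pad_factor)
  pk <- dominant_peak(sp, band = c(1 / band_um[2], 1 / band_um[1]))
  list(repeat_um = 1 / pk$frequency, prominence = pk$prominence,
       at_edge = pk$at_edge)
}

#' Myofibril width from the vertical autocorrelation minimum
#'
#' The width is read directly as the lag of the first local minimum of the
#' vertical intensity profile of the image autocorrelation. For a 50\% duty
#' cycle (fibril width = half the inter-fibril period) this equals the true
#' width; at other duty cycles the first minimum tracks the spacing
#' geometry rather than the width alone — a documented property of the
#' estimator, not of any particular image.
#'
#' @param roi an [image2d] with fibrils horizontal.
#' @param smooth_halfwidth moving-average half-width applied to the profile
#'   before minimum search (default 1).
#' @return List with `width_um` (NA when no minimum exists) and
#'   `minimum_found` (logical).
#' @export
estimate_width <- function(roi, smooth_halfwidth = 1L) {
  assert_image2d(roi)
  prof <- axis_profile(autocorrelate_2d(roi), "vertical")
  w <- tryCatch(
    first_local_minimum(prof, smooth_halfwidth = smooth_halfwidth),
    myofq_no_minimum = function(e) NA_real_)
  list(width_um = w, minimum_found = is.finite(w))
}

#' Full lengthwise analysis: repeat and width over nine ROIs
#'
#' Orients the image so fibrils run horizontally, tiles it into a grid of
#' ROIs (nine by default) and reports the sarcomere repeat and myofibril
#' width per ROI together with summary statistics over the ROIs that
#' yielded an estimate. Individual ROI failures are recorded in the result
#' table rather than silently dropped; the analysis errors out only when
#' fewer than `min_ok` ROIs survive.
#'
#' @param img an [image2d].
#' @param band_um period search band, see [estimate_repeat()].
#' @param grid ROI grid, see [orient_and_tile()].
#' @param rotate_deg optional manual rotation override.
#' @param smooth_halfwidth see [estimate_width()].
#' @param min_ok minimum number of ROIs with a valid repeat (default 5).
#' @return An object of class `lengthwise_result`: list with `per_roi`
#'   (data.frame: roi, repeat_um, width_um, prominence, minimum_found,
#'   note), `summary` (mean/median/sd of each metric), `rotation_deg`,
#'   `n_roi_ok`, `pixel_size_um`.
#' @export
analyze_lengthwise <- function(img, band_um = c(1, 5), grid = c(3L, 3L),
                               rotate_deg = NULL, smooth_halfwidth = 1L,
                               min_ok = 5L) {
  assert_image2d(img)
  if (stats::var(as.numeric(img$pixels)) == 0)
    stop_degenerate("blank (constant) image: nothing to analyse")
  rs <- orient_and_tile(img, grid = grid, rotate_deg = rotate_deg)
  n <- length(rs$rois)
  per <- data.frame(roi = seq_len(n), repeat_um = NA_real_,
                    width_um = NA_real_, prominence = NA_real_,
                    minimum_found = FALSE, note = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rep_i <- tryCatch(estimate_repeat(rs$rois[[i]], band_um = band_um),
                      myofq_error = function(e) conditionMessage(e))
    if (is.list(rep_i)) {
      per$repeat_um[i] <- rep_i$repeat_um
      per$prominence[i] <- rep_i$prominence
      if (rep_i$at_edge) per$note[i] <- "peak at band edge"
    } else {
      per$note[i] <- rep_i
    }
    wid_i <- tryCatch(estimate_width(rs$rois[[i]],
                                     smooth_halfwidth = smooth_halfwidth),
                      myofq_error = function(e) NULL)
    if (!is.null(wid_i)) {
      per$width_um[i] <- wid_i$width_um
      per$minimum_found[i] <- wid_i$minimum_found
    }
  }
  ok <- is.finite(per$repeat_um)
  if (sum(ok) < min_ok)
    myofq_stop(paste0(
      sprintf("only %d of %d ROIs produced a repeat estimate (need >= %d):\n",
              sum(ok), n, min_ok),
      paste(sprintf("  ROI %d: %s", per$roi[!ok],
                    ifelse(per$note[!ok] == "", "no estimate",
                           per$note[!ok])), collapse = "\n")),
      "myofq_analysis_error")
  summ <- data.frame(
    metric = c("repeat_um", "width_um"),
    mean = c(mean(per$repeat_um[ok]),
             mean(per$width_um[per$minimum_found])),
    median = c(stats::median(per$repeat_um[ok]),
               stats::median(per$width_um[per$minimum_found])),
    sd = c(stats::sd(per$repeat_um[ok]),
           stats::sd(per$width_um[per$minimum_found])),
    n = c(sum(ok), sum(per$minimum_found)),
    stringsAsFactors = FALSE)
  structure(list(per_roi = per, summary = summ,
                 rotation_deg = rs$rotation_deg, n_roi_ok = sum(ok),
                 isotropic = rs$isotropic,
                 pixel_size_um = img$pixel_size_um),
            class = "lengthwise_result")
}

#' @export
print.lengthwise_result <- function(x, ...) {
  cat(sprintf("<lengthwise_result> %d/%d ROIs ok, rotation %.2f deg\n",
              x$n_roi_ok, nrow(x$per_roi), x$rotation_deg))
  cat(sprintf("  repeat: mean %.3f um (median %.3f, sd %.3g, n %d)\n",
              x$summary$mean[1], x$summary$median[1], x$summary$sd[1],
              x$summary$n[1]))
  cat(sprintf("  width : mean %.3f um (median %.3f, sd %.3g, n %d)\n",
              x$summary$mean[2], x$summary$median[2], x$summary$sd[2],
              x$summary$n[2]))
  invisible(x)
}
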