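#' Normalized 2-D autocorrelation of an image
#'
#' Computes the mean-subtracted, circular (wrap-around) autocorrelation via
#' the power spectrum, recentres it so that zero lag sits at the central
#' sample `(floor(nrow/2) + 1, floor(ncol/2) + 1)`, and normalizes so the
#' zero-lag value is exactly 1. The circular (FFT) form is used rather than
#' a zero-padded linear ACF; this matches common plug-in practice and keeps
#' the unit normalization simple.
#'
#' Mean subtraction is applied first so that the DC component does not mask
#' the minima and peaks the downstream estimators look for; a consequence is
#' that all outputs are invariant under affine intensity rescaling
#' `a*I + b`, `a > 0`.
#'
#' @param img an [image2d].
#' @return An object of class `acf_map`: list with `values` (matrix, same
#'   shape as the image), `pixel_size_um`, and `center` (1-based row/col of
#'   the zero-lag sample).
#' @seealso [radial_average()], [axis_profile()]
#' @examples
#' x <- outer(rep(1, 32), cos(2 * pi * (0:31) / 16))
#' a <- autocorrelate_2d(image2d(x - min(x), 0.05))
#' a$values[a$center[1], a$center[2]]  # 1 at zero lag
#' @export
autocorrelate_2d <- function(img) {
  assert_image2d(img)
  x <- img$pixels - mean(img$pixels)
  if (sum(x^2) == 0)
    stop_degenerate(
      "zero-variance (constant) image: autocorrelation undefined")
  P <- Mod(stats::fft(x))^2
  a <- Re(stats::fft(P, inverse = TRUE)) / length(x)
  a <- a / a[1, 1]
  a <- a[fftshift_index(nrow(a)), fftshift_index(ncol(a))]
  structure(list(values = a, pixel_size_um = img$pixel_size_um,
                 center = c(center_index(nrow(a)), center_index(ncol(a)))),
            class = "acf_map")
}

assert_acf_map <- function(map) {
  if (!inherits(map, "acf_map"))
    myofq_stop("expected an `acf_map` (see autocorrelate_2d)",
               "myofq_type_error")
  invisible(map)
}

#' @export
print.acf_map <- function(x, ...) {
  cat(sprintf("<acf_map> %d x %d, zero lag at (%d, %d), %.4g um/px\n",
              nrow(x$values), ncol(x$values), x$center[1], x$center[2],
              x$pixel_size_um))
  invisible(x)
}

#' Radial average profile of an autocorrelation map
#'
#' Bins the map samples by Euclidean lag from zero: `values[k]` is the mean
#' over samples whose lag falls in `[k*b, (k+1)*b)` pixels. The axis is the
#' bin centre converted to micrometres. Empty bins are dropped (never
#' interpolated).
#'
#' @param map an `acf_map` from [autocorrelate_2d()].
#' @param bin_width_px bin width in pixels, >= 0.5 (default 1).
#' @return A [profile1d] of kind `"radial_acf"`.
#' @export
radial_average <- function(map, bin_width_px = 1) {
  assert_acf_map(map)
  if (!is.numeric(bin_width_px) || bin_width_px < 0.5)
    myofq_stop("`bin_width_px` must be >= 0.5", "myofq_type_error")
  radial_profile_about(map$values, map$center, bin_width_px,
                       map$pixel_size_um, kind = "radial_acf")
}

#' Axial profile of an autocorrelation map through zero lag
#'
#' The 1-D slice along the requested axis through the zero-lag sample,
#' non-negative lags only. The vertical profile (lags along rows) is the
#' basis of the myofibril width estimator.
#'
#' @param map an `acf_map`.
#' @param axis `"vertical"` (along rows) or `"horizontal"` (along columns).
#' @return A [profile1d]; `ceiling(n/2)` samples for an axis of length `n`,
#'   axis in micrometres starting at lag 0.
#' @export
axis_profile <- function(map, axis = c("vertical", "horizontal")) {
  assert_acf_map(map)
  axis <- match.arg(axis)
  if (axis == "vertical") {
    v <- map$values[map$center[1]:nrow(map$values), map$center[2]]
    kind <- "vertical_acf"
  } else {
    v <- map$values[map$center[1], map$center[2]:ncol(map$values)]
    kind <- "horizontal_acf"
  }
  profile1d(axis = (seq_along(v) - 1) * map$pixel_size_um,
            values = v, kind = kind, unit = "um")
}

#' Power spectrum along the horizontal frequency axis
#'
#' Mean-subtracts the image, optionally applies a Hann window along each
#' row, takes the 2-D discrete Fourier transform and averages the power over
#' all vertical frequencies, yielding one power value per horizontal spatial
#' frequency. Positive frequencies only; the DC column is excluded.
#'
#' The Hann window (the default in the high-level estimators) reduces
#' spectral leakage when the image holds a non-integer number of periods;
#' `window = "none"` preserves the exact single-bin concentration of an
#' integer-period tone. `pad_factor > 1` zero-pads each row before the
#' transform, refining the frequency grid for sub-bin peak interpolation
#' (at the cost of sinc sidelobes when used without a window).
#'
#' @param img an [image2d]; fibrils are assumed to run horizontally.
#' @param window `"hann"` or `"none"`.
#' @param pad_factor integer >= 1; horizontal zero-padding factor.
#' @return A [profile1d] of kind `"horizontal_spectrum"`, axis in
#'   cycles/micrometre.
#' @export
horizontal_power_spectrum <- function(img, window = c("hann", "none"),
                                      pad_factor = 1L) {
  assert_image2d(img)
  window <- match.arg(window)
  pad_factor <- as.integer(pad_factor)
  if (pad_factor < 1L)
    myofq_stop("`pad_factor` must be >= 1", "myofq_type_error")
  x <- img$pixels - mean(img$pixels)
  if (sum(x^2) == 0)
    stop_degenerate("zero-variance (constant) image: spectrum undefined")
  nc <- ncol(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(nc - 1)) / (nc - 1))
    x <- sweep(x, 2L, w, "*")
  }
  ncp <- nc * pad_factor
  if (pad_factor > 1L)
    x <- cbind(x, matrix(0, nrow(x), ncp - nc))
  P <- Mod(stats::fft(x))^2
  pw <- colMeans(P)
  kmax <- floor(ncp / 2)
  freq <- (1:kmax) / (ncp * img$pixel_size_um)
  profile1d(axis = freq, values = pw[2:(kmax + 1L)],
            kind = "horizontal_spectrum", unit = "cycles_per_um")
}

#' First local minimum of a 1-D profile
#'
#' After optional moving-average smoothing (window `2h + 1`), finds the
#' smallest index `k > 0` with `values[k] <= values[k-1]` and
#' `values[k] < values[k+1]` (ties broken toward smaller lag), then refines
#' the position to sub-sample precision by parabolic interpolation through
#' the three samples around the minimum.
#'
#' @param p a [profile1d] with >= 5 samples.
#' @param smooth_halfwidth integer >= 0; moving-average half-width.
#' @return The axis value (in the profile's units) of the refined minimum.
#'   Raises a `myofq_no_minimum` condition when the profile has no interior
#'   local minimum (e.g. is monotonically non-increasing throughout).
#' @export
first_local_minimum <- function(p, smooth_halfwidth = 0L) {
  if (!inherits(p, "profile1d"))
    myofq_stop("`p` must be a profile1d", "myofq_type_error")
  if (length(p$values) < 5L)
    myofq_stop("profile must have at least 5 samples", "myofq_size_error")
  v <- moving_average(p$values, smooth_halfwidth)
  n <- length(v)
  k <- NA_integer_
  for (i in 2:(n - 1L)) {
    if (v[i] <= v[i - 1L] && v[i] < v[i + 1L]) { k <- i; break }
  }
  if (is.na(k))
    stop_no_minimum("profile has no interior local minimum")
  delta <- parabolic_offset(v[k - 1L], v[k], v[k + 1L])
  step <- if (delta >= 0) {
    p$axis[min(k + 1L, n)] - p$axis[k]
  } else {
    p$axis[k] - p$axis[k - 1L]
  }
  p$axis[k] + delta * step
}

#' Dominant spectral peak within a frequency band
#'
#' Restricts the profile to `[f_lo, f_hi]`, takes the argmax (ties broken
#' toward lower frequency), and refines the peak position by parabolic
#' interpolation over the log-power of the three bins around the maximum.
#' Peaks falling on a band or profile edge are returned unrefined and
#' flagged. The prominence QC score is peak power divided by the median
#' in-band power.
#'
#' @param p a [profile1d] of kind `"horizontal_spectrum"`.
#' @param band numeric length-2, `c(f_lo, f_hi)` in the profile's axis
#'   units, `f_lo < f_hi`.
#' @return List with `frequency` (refined, cycles/um), `prominence`, and
#'   `at_edge` (logical QC flag).
#' @export
dominant_peak <- function(p, band) {
  if (!inherits(p, "profile1d"))
    myofq_stop("`p` must be a profile1d", "myofq_type_error")
  if (length(band) != 2L || band[1] >= band[2])
    myofq_stop("`band` must be c(f_lo, f_hi) with f_lo < f_hi",
               "myofq_band_error")
  sel <- which(p$axis >= band[1] & p$axis <= band[2])
  if (length(sel) == 0L)
    myofq_stop(sprintf(
      "no spectral sample inside band [%g, %g] (axis spans [%g, %g])",
      band[1], band[2], p$axis[1], p$axis[length(p$axis)]),
      "myofq_band_error")
  j <- sel[which.max(p$values[sel])]
  at_edge <- j == sel[1] || j == sel[length(sel)] ||
    j == 1L || j == length(p$values)
  freq <- p$axis[j]
  if (!at_edge) {
    y <- p$values[(j - 1L):(j + 1L)]
    if (all(y > 0)) {
      delta <- parabolic_offset(log(y[1]), log(y[2]), log(y[3]))
      step <- if (delta >= 0) p$axis[j + 1L] - p$axis[j]
              else p$axis[j] - p$axis[j - 1L]
      freq <- freq + delta * step
    }
  }
  prom <- p$values[j] / stats::median(p$values[sel])
  list(frequency = freq, prominence = prom, at_edge = at_edge)
}
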