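#' 2-D intensity image with physical pixel size
#'
#' The universal input container: a matrix of non-negative fluorescence
#' intensities (rows = y, increasing downwards; columns = x) plus the
#' physical edge length of one (isotropic) pixel in micrometres. The
#' convention used throughout the package is 0-based (row, col) coordinates
#' with pixel centres at integer coordinates.
#'
#' @param pixels numeric matrix of intensities, at least 16 x 16, all finite
#'   and non-negative.
#' @param pixel_size_um positive scalar, micrometres per pixel.
#' @param label optional character label (e.g. channel or developmental
#'   stage).
#' @param provenance optional list recording where the image came from
#'   (file path, bit depth, pixel-size source); attached as-is.
#'
#' @return An object of class `image2d`: a list with elements `pixels`,
#'   `pixel_size_um`, `label`, `provenance`.
#' @examples
#' img <- image2d(matrix(runif(32 * 32), 32), pixel_size_um = 0.05)
#' dim(img)
#' @export
image2d <- function(pixels, pixel_size_um, label = NULL, provenance = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    myofq_stop("`pixels` must be a numeric matrix", "myofq_type_error")
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    myofq_stop(sprintf(
      "image must be at least 16 x 16 pixels (got %d x %d)",
      nrow(pixels), ncol(pixels)), "myofq_size_error")
  if (!all(is.finite(pixels)))
    myofq_stop("image contains non-finite intensities", "myofq_type_error")
  if (any(pixels < 0))
    myofq_stop("image contains negative intensities", "myofq_type_error")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    myofq_stop("`pixel_size_um` must be a single positive number",
               "myofq_type_error")
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         label = label, provenance = provenance),
    class = "image2d")
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.4g um/px (%.3g x %.3g um)%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              nrow(x$pixels) * x$pixel_size_um,
              ncol(x$pixels) * x$pixel_size_um,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

assert_image2d <- function(img, arg = "img") {
  if (!inherits(img, "image2d"))
    myofq_stop(sprintf("`%s` must be an image2d object", arg),
               "myofq_type_error")
  invisible(img)
}

#' 1-D sampled profile with physical axis
#'
#' Holds radial/axial autocorrelation profiles (axis in micrometres of lag)
#' and 1-D power spectra (axis in cycles per micrometre).
#'
#' @param axis strictly increasing numeric vector of physical coordinates.
#' @param values numeric vector, same length as `axis` (length >= 3).
#' @param kind one of `"radial_acf"`, `"vertical_acf"`, `"horizontal_acf"`,
#'   `"horizontal_spectrum"`, `"radial_intensity"`.
#' @param unit axis unit, `"um"` or `"cycles_per_um"`.
#' @return An object of class `profile1d`.
#' @export
profile1d <- function(axis, values,
                      kind = c("radial_acf", "vertical_acf",
                               "horizontal_acf", "horizontal_spectrum",
                               "radial_intensity"),
                      unit = c("um", "cycles_per_um")) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  if (length(axis) != length(values) || length(axis) < 3L)
    myofq_stop("`axis` and `values` must have equal length >= 3",
               "myofq_type_error")
  if (any(diff(axis) <= 0))
    myofq_stop("`axis` must be strictly increasing", "myofq_type_error")
  structure(list(axis = as.numeric(axis), values = as.numeric(values),
                 kind = kind, unit = unit),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %s, %d samples, axis [%.4g, %.4g] %s\n",
              x$kind, length(x$axis), x$axis[1],
              x$axis[length(x$axis)], x$unit))
  invisible(x)
}
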