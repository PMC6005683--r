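#' Sarcomeres per fibril
#'
#' Average individual fiber length divided by sarcomere length. Reported as
#' a real number; rounding is left to the presentation layer.
#'
#' @param fiber_length_um fiber length in micrometres (> 0).
#' @param sarcomere_length_um sarcomere repeat in micrometres (> 0).
#' @return The ratio (real-valued count).
#' @examples
#' sarcomeres_per_fibril(480, 2.0)  # 240
#' @export
sarcomeres_per_fibril <- function(fiber_length_um, sarcomere_length_um) {
  if (!is.numeric(fiber_length_um) || any(fiber_length_um <= 0) ||
      !is.numeric(sarcomere_length_um) || any(sarcomere_length_um <= 0))
    myofq_stop("both lengths must be positive", "myofq_domain_error")
  fiber_length_um / sarcomere_length_um
}

#' Fibrils per fiber
#'
#' Average number of fibrils per unit cross-sectional area multiplied by
#' the individual fiber cross-sectional area.
#'
#' @param density_per_um2 fibril density per square micrometre (>= 0).
#' @param cross_area_um2 fiber cross-sectional area in um^2 (>= 0).
#' @return The product (real-valued count).
#' @examples
#' fibrils_per_fiber(0.25, 6970)  # 1742.5
#' @export
fibrils_per_fiber <- function(density_per_um2, cross_area_um2) {
  if (!is.numeric(density_per_um2) || any(density_per_um2 < 0) ||
      !is.numeric(cross_area_um2) || any(cross_area_um2 < 0))
    myofq_stop("density and area must be non-negative", "myofq_domain_error")
  density_per_um2 * cross_area_um2
}

#' Bead-normalized fluorescence intensity
#'
#' Relative fiber-to-bead fluorescence for one image: the mean of three
#' fiber ROI intensities divided by the mean of three bead ROI
#' intensities.
#'
#' @param fiber_means numeric vector of exactly three fiber ROI means.
#' @param bead_means numeric vector of exactly three bead ROI means; their
#'   mean must be positive.
#' @return The ratio.
#' @export
bead_normalized_intensity <- function(fiber_means, bead_means) {
  if (length(fiber_means) != 3L || length(bead_means) != 3L)
    myofq_stop("exactly three fiber and three bead ROI means are required",
               "myofq_domain_error")
  mb <- mean(bead_means)
  if (!is.finite(mb) || mb <= 0)
    myofq_stop("bead mean must be positive", "myofq_domain_error")
  mean(fiber_means) / mb
}

#' Tukey box summary
#'
#' Quartiles by linear interpolation (the type-7 convention of
#' [stats::quantile()]); whiskers at the most extreme data points within
#' `q1 - 1.5 * IQR` and `q3 + 1.5 * IQR`; points beyond the fences are
#' listed as outliers. A constant sample yields a degenerate zero-IQR
#' summary with whiskers at the median.
#'
#' @param values numeric vector, at least 4 finite values.
#' @return An object of class `box_summary`: list with `median`, `q1`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `outliers`, `n`.
#' @examples
#' box_summary(1:9)
#' @export
box_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    myofq_stop("at least 4 finite values are required", "myofq_domain_error")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = min(values[inside]),
                 whisker_hi = max(values[inside]),
                 outliers = sort(values[!inside]), n = length(values)),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary> n=%d median %.4g [q1 %.4g, q3 %.4g], whiskers [%.4g, %.4g]",
    x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi))
  if (length(x$outliers))
    cat(sprintf(", %d outlier(s)", length(x$outliers)))
  cat("\n")
  invisible(x)
}
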