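#' Read a grayscale micrograph with its pixel size
#'
#' Reads a single-plane grayscale TIFF (8/16-bit) or PNG into an
#' [image2d]. The pixel size is taken from the TIFF resolution metadata
#' when present; otherwise `pixel_size_um` is required — a missing pixel
#' size is always an explicit error, never a silent default. An explicit
#' `pixel_size_um` always wins over metadata and is recorded as an
#' override. Multi-channel images and stacks require `channel` / `slice`.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um optional pixel size override in micrometres.
#' @param channel channel index for multi-channel images.
#' @param slice directory/slice index for multi-page TIFFs.
#' @return An [image2d] with a `provenance` list (path, bit depth,
#'   pixel-size source).
#' @export
read_image <- function(path, pixel_size_um = NULL, channel = NULL,
                       slice = NULL) {
  if (!file.exists(path))
    myofq_stop(sprintf("file not found: %s", path), "myofq_io_error")
  ext <- tolower(tools::file_ext(path))
  meta_px <- NULL
  bits <- NA_integer_
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
    if (length(pages) > 1L) {
      if (is.null(slice))
        myofq_stop(sprintf(
          "TIFF has %d slices; pass `slice` to pick one", length(pages)),
          "myofq_io_error")
      arr <- pages[[slice]]
    } else arr <- pages[[1L]]
    info <- attributes(arr)
    bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample[1]
            else NA_integer_
    if (!is.null(info$x.resolution) && info$x.resolution > 0) {
      unit <- if (!is.null(info$resolution.unit)) info$resolution.unit
              else "inch"
      per_um <- switch(as.character(unit),
                       inch = info$x.resolution / 25400,
                       cm = info$x.resolution / 10000,
                       NULL)
      if (!is.null(per_um) && per_um > 0) meta_px <- 1 / per_um
    }
  } else if (ext == "png") {
    arr <- png::readPNG(path)
  } else {
    myofq_stop(sprintf("unsupported image format: .%s", ext),
               "myofq_io_error")
  }
  if (length(dim(arr)) == 3L) {
    if (is.null(channel))
      myofq_stop(sprintf(
        "image has %d channels; pass `channel` to pick one", dim(arr)[3]),
        "myofq_io_error")
    arr <- arr[, , channel]
  }
  src <- if (!is.null(pixel_size_um)) "override"
         else if (!is.null(meta_px)) "tiff_metadata"
         else myofq_stop(paste0(
           "pixel size unknown: no resolution metadata in file and no ",
           "`pixel_size_um` given"), "myofq_io_error")
  psz <- if (!is.null(pixel_size_um)) pixel_size_um else meta_px
  image2d(arr * 1.0, psz,
          provenance = list(path = path, bits_per_sample = bits,
                            pixel_size_source = src))
}

#' Write an image (and optional ground truth) to disk
#'
#' Writes a 16-bit grayscale TIFF (intensities scaled to the full 16-bit
#' range) plus a JSON sidecar (same path with `.json` appended) holding the
#' pixel size, the intensity scale and any ground-truth record — the
#' format the phantom subcommand uses. The sidecar is the authoritative
#' pixel-size carrier.
#'
#' @param img an [image2d].
#' @param path output `.tif` path.
#' @param sidecar optional list merged into the sidecar record.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, sidecar = NULL) {
  assert_image2d(img)
  mx <- max(img$pixels)
  scaled <- if (mx > 0) img$pixels / mx else img$pixels
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L,
                  compression = "none")
  rec <- c(list(pixel_size_um = img$pixel_size_um, intensity_max = mx),
           sidecar)
  jsonlite::write_json(rec, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Results of an analysis as a long-format table
#'
#' One row per ROI per metric plus one summary row per metric for
#' lengthwise results; count/diameter/density/d0 rows for crosswise
#' results. Columns: `file`, `stage`, `tool`, `roi`, `metric`, `value`,
#' `unit`, `qc`, `note`.
#'
#' @param result a `lengthwise_result` or `crosswise_result`.
#' @param file source file label (default `""`).
#' @param stage stage label (default `""`).
#' @return data.frame in the schema above.
#' @export
results_table <- function(result, file = "", stage = "") {
  row <- function(tool, roi, metric, value, unit, qc = NA_real_,
                  note = "") {
    data.frame(file = file, stage = stage, tool = tool, roi = roi,
               metric = metric, value = value, unit = unit, qc = qc,
               note = note, stringsAsFactors = FALSE)
  }
  if (inherits(result, "lengthwise_result")) {
    p <- result$per_roi
    out <- rbind(
      do.call(rbind, lapply(seq_len(nrow(p)), function(i)
        row("lengthwise", p$roi[i], "repeat", p$repeat_um[i], "um",
            p$prominence[i], p$note[i]))),
      do.call(rbind, lapply(seq_len(nrow(p)), function(i)
        row("lengthwise", p$roi[i], "width", p$width_um[i], "um",
            note = if (p$minimum_found[i]) "" else "no minimum"))),
      row("lengthwise", NA_integer_, "repeat_mean",
          result$summary$mean[1], "um"),
      row("lengthwise", NA_integer_, "width_mean",
          result$summary$mean[2], "um"))
    return(out)
  }
  if (inherits(result, "crosswise_result")) {
    return(rbind(
      row("crosswise", NA_integer_, "n_detected", result$n_detected,
          "count"),
      row("crosswise", NA_integer_, "diameter", result$diameter_um, "um"),
      row("crosswise", NA_integer_, "d0", result$d0_um, "um",
          note = if (result$d0_fallback) "fallback" else ""),
      row("crosswise", NA_integer_, "density", result$density_per_um2,
          "per_um2")))
  }
  myofq_stop("unsupported result type", "myofq_type_error")
}

#' Write analysis results to CSV (with optional QC figures)
#'
#' Writes the long-format table of [results_table()] — or a pre-built
#' data.frame in that schema, possibly empty — as CSV. Identical results
#' yield byte-identical CSVs. When `qc_prefix` is given, QC overlay PNGs
#' are also written: the horizontal power spectrum with the detected peak
#' marked (lengthwise) or the detected centres and the radial profile with
#' its 26\% crossing (crosswise).
#'
#' @param results a result object or data.frame.
#' @param path output CSV path.
#' @param file,stage labels forwarded to [results_table()].
#' @param qc_prefix optional path prefix for QC PNGs.
#' @param qc_image the analysed [image2d], required for the crosswise
#'   overlay PNG.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, file = "", stage = "",
                          qc_prefix = NULL, qc_image = NULL) {
  tab <- if (is.data.frame(results)) results
         else results_table(results, file = file, stage = stage)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    myofq_stop(sprintf("cannot write %s: %s", path,
                       conditionMessage(ok)), "myofq_io_error")
  if (!is.null(qc_prefix) && !is.data.frame(results))
    write_qc(results, qc_prefix, qc_image = qc_image)
  invisible(path)
}

# QC overlay figures mirroring the plug-in's visual-inspection output.
write_qc <- function(result, prefix, qc_image = NULL) {
  if (inherits(result, "crosswise_result")) {
    if (!is.null(qc_image)) {
      grDevices::png(paste0(prefix, "_centers.png"), 800, 800)
      op <- graphics::par(mar = c(2, 2, 2, 1))
      image_show(qc_image, main = sprintf("%d detected cross-sections",
                                          result$n_detected))
      graphics::points(result$centers[, 2] + 1, result$centers[, 1] + 1,
                       col = "red", pch = 3, cex = 0.7)
      graphics::par(op)
      grDevices::dev.off()
    }
    grDevices::png(paste0(prefix, "_radial.png"), 700, 500)
    p <- result$radial_profile
    graphics::plot(p$axis, p$values, type = "l", xlab = "radius (um)",
                   ylab = "mean intensity",
                   main = sprintf("radial profile; diameter %.3f um",
                                  result$diameter_um))
    graphics::abline(h = result$threshold, lty = 2, col = "grey40")
    graphics::abline(v = result$diameter_um / 2, col = "red")
    grDevices::dev.off()
  } else if (inherits(result, "lengthwise_result") && !is.null(qc_image)) {
    sp <- horizontal_power_spectrum(qc_image, window = "hann")
    grDevices::png(paste0(prefix, "_spectrum.png"), 700, 500)
    graphics::plot(sp$axis, sp$values, type = "l", log = "y",
                   xlab = "spatial frequency (cycles/um)", ylab = "power",
                   main = sprintf("repeat %.3f um (mean over %d ROIs)",
                                  result$summary$mean[1], result$n_roi_ok))
    graphics::abline(v = 1 / result$summary$mean[1], col = "red")
    grDevices::dev.off()
  }
  invisible(NULL)
}

# Display an image2d with base graphics, y axis pointing down.
image_show <- function(img, ...) {
  m <- img$pixels
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m)[, nrow(m):1],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "", ylab = "", ...)
}

#' Build and validate a run configuration
#'
#' Collects the tunable parameters of both analysis tools with their
#' defaults, validates them, and (optionally) loads overrides from a YAML
#' file. Every defaulted field is part of the returned record so a run log
#' documents the full configuration, not just the overrides.
#'
#' @param yaml_path optional YAML file of overrides.
#' @param ... named overrides applied after the YAML file.
#' @return A validated named list of class `run_config`.
#' @export
run_config <- function(yaml_path = NULL, ...) {
  cfg <- list(pixel_size_um = NULL, band_um = c(1, 5), grid = c(3L, 3L),
              rotate_deg = NULL, smooth_halfwidth = 1L, fraction = 0.26,
              range_anchor = "min", k_mad = 5, min_sep_factor = 0.8,
              crop_factor = 2, fallback_d0_um = 1.0, seed = 1L)
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path))
      myofq_stop(sprintf("config file not found: %s", yaml_path),
                 "myofq_io_error")
    over <- yaml::read_yaml(yaml_path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!is.null(cfg$pixel_size_um) && cfg$pixel_size_um <= 0)
    myofq_stop("pixel_size_um must be positive", "myofq_type_error")
  if (length(cfg$band_um) != 2L || cfg$band_um[1] >= cfg$band_um[2])
    myofq_stop("band_um must be c(min_period, max_period)",
               "myofq_band_error")
  if (!cfg$range_anchor %in% c("min", "zero"))
    myofq_stop("range_anchor must be 'min' or 'zero'", "myofq_type_error")
  structure(cfg, class = "run_config")
}

#' Write the machine-readable config echo for a run
#'
#' @param cfg a `run_config`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
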