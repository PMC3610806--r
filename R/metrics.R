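# Bench measurements: calibrated fibre-transmission units and the
# histogram-quantile contrast averaged over the seven line frequencies.
#
# Contrast is a pure histogram statistic: pixels inside the ROI disc are
# accumulated in ascending grey order and contrast is the grey-level
# distance between the points where the cumulative count reaches 25% and
# 75% of the ROI pixel count.

new_roi_spec <- function(center, radius) {
  structure(list(center = center, radius = radius), class = "endo_roi")
}

# 4-connected component labelling by iterative min-label propagation on the
# binary image; adequate for the bench's single bright disc.
label_components <- function(bw) {
  lab <- matrix(NA_integer_, nrow(bw), ncol(bw))
  lab[bw] <- which(bw)
  n <- nrow(bw); m <- ncol(bw)
  repeat {
    nb <- lab
    nb[-1, ] <- pmin(nb[-1, ], lab[-n, ], na.rm = TRUE)
    nb[-n, ] <- pmin(nb[-n, ], lab[-1, ], na.rm = TRUE)
    nb[, -1] <- pmin(nb[, -1], lab[, -m], na.rm = TRUE)
    nb[, -m] <- pmin(nb[, -m], lab[, -1], na.rm = TRUE)
    nb[!bw] <- NA_integer_
    if (identical(nb, lab)) break
    lab <- nb
  }
  lab
}

#' Locate the region of interest from a rendered ROI-circle capture
#'
#' Thresholds the capture at the midpoint between its 10th and 90th grey
#' percentiles and takes the largest bright connected component; the ROI is
#' its centroid and equivalent-area radius. The detection survives blur
#' (the disc centroid is preserved under a symmetric point spread).
#'
#' @param roi_image integer matrix: a capture of the `ROI_CIRCLE` pattern.
#' @return an `endo_roi` with `center = c(row, col)` and `radius` in px.
#' @export
locate_roi <- function(roi_image) {
  if (!is.matrix(roi_image)) abort_endoqc("`roi_image` must be a matrix")
  q <- stats::quantile(roi_image, c(0.1, 0.9), names = FALSE)
  bw <- roi_image > mean(q)
  min_px <- 0.005 * length(roi_image)
  if (sum(bw) < min_px) {
    abort_endoqc("no bright region covering >= 0.5% of pixels",
                 "endoqc_roi_not_found")
  }
  lab <- label_components(bw)
  sizes <- table(lab[!is.na(lab)])
  if (max(sizes) < min_px) {
    abort_endoqc("no bright component covering >= 0.5% of pixels",
                 "endoqc_roi_not_found")
  }
  keep <- lab == as.integer(names(sizes)[which.max(sizes)])
  keep[is.na(keep)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  new_roi_spec(center = c(mean(idx[, 1]), mean(idx[, 2])),
               radius = sqrt(nrow(idx) / pi))
}

roi_pixels <- function(image, roi) {
  n <- nrow(image); m <- ncol(image)
  d2 <- outer((seq_len(n) - roi$center[1])^2,
              (seq_len(m) - roi$center[2])^2, `+`)
  image[d2 <= roi$radius^2]
}

#' Histogram-quantile contrast inside the ROI
#'
#' Let N be the ROI pixel count and build the cumulative histogram of grey
#' levels in ascending order. With `g25` the smallest grey level whose
#' cumulative count reaches `ceiling(0.25 N)` and `g75` likewise for
#' `ceiling(0.75 N)`, the contrast is `g75 - g25` grey levels. No
#' interpolation is used; the statistic depends only on the ROI histogram.
#'
#' @param image integer matrix of grey levels 0..255.
#' @param roi an `endo_roi` from [locate_roi()].
#' @return contrast in grey levels, 0..255.
#' @export
compute_contrast <- function(image, roi) {
  if (!inherits(roi, "endo_roi")) abort_endoqc("`roi` must be an endo_roi")
  px <- roi_pixels(image, roi)
  n <- length(px)
  if (n == 0L) abort_endoqc("ROI contains no pixels")
  cs <- cumsum(tabulate(as.integer(px) + 1L, nbins = 256L))
  g25 <- which(cs >= ceiling(0.25 * n))[1L] - 1L
  g75 <- which(cs >= ceiling(0.75 * n))[1L] - 1L
  g75 - g25
}

#' Average contrast over the seven line frequencies
#'
#' @param per_frequency numeric vector of exactly 7 contrast values.
#' @return list with `per_frequency` and their arithmetic `average`.
#' @export
average_contrast <- function(per_frequency) {
  if (length(per_frequency) != 7L) {
    abort_endoqc(sprintf("expected 7 per-frequency contrasts, got %d",
                         length(per_frequency)))
  }
  if (any(per_frequency < 0 | per_frequency > 255)) {
    abort_endoqc("contrast values must be in [0, 255]")
  }
  structure(list(per_frequency = as.numeric(per_frequency),
                 average = mean(per_frequency)),
            class = "endo_contrast")
}

#' Transmission in calibrated units
#'
#' Full scale (100 units) is defined by the calibration signal measured
#' with the light source directly on the photocell; a reading through the
#' endoscope is reported as `100 * endoscope_signal / calibration_signal`.
#'
#' @param reading an `endo_reading`.
#' @return list with `units`, `calibration_signal`, `endoscope_signal`.
#' @export
compute_transmission <- function(reading) {
  if (!inherits(reading, "endo_reading")) {
    abort_endoqc("`reading` must be an endo_reading")
  }
  if (!is.finite(reading$calibration_signal) ||
      reading$calibration_signal <= 0) {
    abort_endoqc("calibration signal must be > 0",
                 "endoqc_calibration_failure")
  }
  if (reading$endoscope_signal < 0) {
    abort_endoqc("endoscope signal must be >= 0")
  }
  structure(list(
    units = 100 * reading$endoscope_signal / reading$calibration_signal,
    calibration_signal = reading$calibration_signal,
    endoscope_signal = reading$endoscope_signal),
    class = "endo_transmission")
}

#' Run the full measurement on one set of captures
#'
#' One bench session for one endoscope: locate the ROI from the circle
#' capture, compute the contrast of each of the seven line captures inside
#' that ROI, average them, convert the photocell reading to transmission
#' units, and assemble an (unstored) measurement record.
#'
#' @param line_captures list of exactly 7 captures (integer matrices), in
#'   frequency order.
#' @param roi_capture capture of the ROI-circle pattern, same dimensions.
#' @param reading an `endo_reading`.
#' @param moisture_observed logical result of the physical cold-spray
#'   check (recorded, not computed from images).
#' @param serial,type_id,timestamp,context record identification fields.
#' @return an `endo_record` (see [measurement_record()]) with the contrast
#'   detail attached as attribute `"contrast_detail"`.
#' @export
measure_endoscope <- function(line_captures, roi_capture, reading,
                              moisture_observed = FALSE,
                              serial = "unknown", type_id = "unknown",
                              timestamp = Sys.time(), context = "CLINICAL") {
  if (length(line_captures) != 7L) {
    abort_endoqc("expected 7 line captures")
  }
  dims <- unique(lapply(c(line_captures, list(roi_capture)), dim))
  if (length(dims) != 1L) {
    abort_endoqc("captures must share identical dimensions")
  }
  roi <- locate_roi(roi_capture)
  contrasts <- vapply(line_captures, compute_contrast, numeric(1), roi = roi)
  cres <- average_contrast(contrasts)
  tres <- compute_transmission(reading)
  rec <- measurement_record(serial = serial, type_id = type_id,
                            timestamp = timestamp,
                            transmission = tres$units,
                            contrast = cres$average,
                            moisture = moisture_observed,
                            context = context)
  attr(rec, "contrast_detail") <- cres
  rec
}
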