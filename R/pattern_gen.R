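# Test-pattern generation: the bench displays alternating black/white line
# patterns at seven spatial frequencies plus a central circle that defines
# the region of interest (ROI) in which sharpness is judged.

PATTERN_KINDS <- c("LINES", "ROI_CIRCLE", "UNIFORM")
ORIENTATIONS <- c("VERTICAL", "HORIZONTAL")

new_test_pattern <- function(pixels, kind, frequency_index = NA_integer_,
                             period_px = NA_integer_,
                             orientation = "VERTICAL") {
  structure(
    list(pixels = pixels, kind = kind,
         frequency_index = frequency_index, period_px = period_px,
         orientation = orientation),
    class = "endo_pattern")
}

#' @export
print.endo_pattern <- function(x, ...) {
  cat(sprintf("<endo_pattern %s %dx%d", x$kind, nrow(x$pixels),
              ncol(x$pixels)))
  if (x$kind == "LINES") {
    cat(sprintf(" f=%d period=%dpx %s", x$frequency_index, x$period_px,
                x$orientation))
  }
  cat(">\n")
  invisible(x)
}

#' Line period for a spatial-frequency index
#'
#' Periods follow a geometric series, `image_size / (4 * 2^(i/2))`, rounded
#' to the nearest even integer (keeping the 50% duty cycle exact) and
#' clamped to >= 2 px. Index 0 is the coarsest pattern.
#'
#' @param frequency_index integer 0..6.
#' @param image_size side length of the square pattern, in pixels.
#' @return even integer period in pixels.
#' @export
line_period <- function(frequency_index, image_size) {
  stopifnot_scalar_number(frequency_index, "frequency_index",
                          min = 0, max = 6, integer = TRUE)
  stopifnot_scalar_number(image_size, "image_size", min = 2, integer = TRUE)
  p <- image_size / (4 * 2^(frequency_index / 2))
  max(2L, 2L * as.integer(round(p / 2)))
}

#' Generate one black/white line pattern
#'
#' Square 8-bit pattern of alternating black (0) and white (255) bars with
#' a 50% duty cycle. `VERTICAL` orientation means the bars are vertical,
#' i.e. grey level varies along the x (column) axis.
#'
#' @param frequency_index integer 0..6; higher index = finer lines.
#' @param image_size side length in pixels.
#' @param orientation `"VERTICAL"` (default) or `"HORIZONTAL"`.
#' @return a `TestPattern` (`endo_pattern`) of kind `LINES`.
#' @examples
#' p <- generate_line_pattern(0, 64)
#' sort(unique(as.vector(p$pixels)))  # 0 255
#' @export
generate_line_pattern <- function(frequency_index, image_size,
                                  orientation = "VERTICAL") {
  orientation <- match.arg(orientation, ORIENTATIONS)
  period <- line_period(frequency_index, image_size)
  if (image_size < 2L * period) {
    abort_endoqc(sprintf(
      "image_size %d cannot hold two periods of %d px (frequency_index %d)",
      image_size, period, frequency_index))
  }
  half <- period %/% 2L
  # bar phase of each pixel along the axis of variation (0-based)
  phase <- ((seq_len(image_size) - 1L) %/% half) %% 2L
  stripe <- ifelse(phase == 0L, 255L, 0L)
  px <- if (orientation == "VERTICAL") {
    matrix(stripe, nrow = image_size, ncol = image_size, byrow = TRUE)
  } else {
    matrix(stripe, nrow = image_size, ncol = image_size)
  }
  new_test_pattern(px, "LINES", as.integer(frequency_index), period,
                   orientation)
}

#' Generate the circular ROI-definition pattern
#'
#' A white disc (255) centred in a black field; its rendered capture is
#' used by [locate_roi()] to fix the region of interest for a measurement
#' session.
#'
#' @param image_size side length in pixels.
#' @param radius_fraction disc radius as a fraction of the half-width,
#'   in (0, 1]. Default 0.4.
#' @return a `TestPattern` of kind `ROI_CIRCLE`.
#' @export
generate_roi_pattern <- function(image_size, radius_fraction = 0.4) {
  stopifnot_scalar_number(image_size, "image_size", min = 2, integer = TRUE)
  if (!is.numeric(radius_fraction) || length(radius_fraction) != 1L ||
      is.na(radius_fraction) || radius_fraction <= 0 || radius_fraction > 1) {
    abort_endoqc("`radius_fraction` must be in (0, 1]")
  }
  ctr <- (image_size + 1) / 2
  radius <- radius_fraction * image_size / 2
  d2 <- outer((seq_len(image_size) - ctr)^2,
              (seq_len(image_size) - ctr)^2, `+`)
  px <- matrix(0L, image_size, image_size)
  px[d2 <= radius^2] <- 255L
  new_test_pattern(px, "ROI_CIRCLE")
}

#' Default bench pattern suite
#'
#' The patterns shown in one measurement session: seven line patterns at
#' frequency indices 0..6 (coarse to fine), followed by one ROI circle.
#'
#' @param image_size side length in pixels; must be large enough that all
#'   seven periods are distinct and each fits at least twice.
#' @param radius_fraction forwarded to [generate_roi_pattern()].
#' @param orientation forwarded to [generate_line_pattern()].
#' @return list of 8 `endo_pattern`s: indices 1..7 are `LINES`
#'   (frequency_index 0..6), index 8 is the `ROI_CIRCLE`.
#' @export
default_pattern_suite <- function(image_size, radius_fraction = 0.4,
                                  orientation = "VERTICAL") {
  periods <- vapply(0:6, line_period, integer(1), image_size = image_size)
  if (any(diff(periods) >= 0L)) {
    abort_endoqc(sprintf(
      "image_size %d is too small: line periods %s are not strictly decreasing",
      image_size, paste(periods, collapse = ",")))
  }
  suite <- lapply(0:6, generate_line_pattern, image_size = image_size,
                  orientation = orientation)
  c(suite, list(generate_roi_pattern(image_size, radius_fraction)))
}

#' Write a pattern (or capture) with its JSON metadata sidecar
#'
#' Emits `<stem>.pgm` plus `<stem>.json` describing kind, frequency index,
#' period and orientation.
#'
#' @param pattern an `endo_pattern`.
#' @param stem output path without extension.
#' @return the PGM path, invisibly.
#' @export
write_pattern <- function(pattern, stem) {
  if (!inherits(pattern, "endo_pattern")) {
    abort_endoqc("`pattern` must be an endo_pattern")
  }
  write_pgm(pattern$pixels, paste0(stem, ".pgm"))
  meta <- list(kind = pattern$kind,
               frequency_index = pattern$frequency_index,
               period_px = pattern$period_px,
               orientation = pattern$orientation)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(paste0(stem, ".pgm"))
}

#' Read a pattern written by [write_pattern()]
#'
#' @param stem path without extension.
#' @return an `endo_pattern`.
#' @export
read_pattern <- function(stem) {
  px <- read_pgm(paste0(stem, ".pgm"))
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  new_test_pattern(
    px, meta$kind,
    if (is.null(meta$frequency_index)) NA_integer_
    else as.integer(meta$frequency_index),
    if (is.null(meta$period_px)) NA_integer_ else as.integer(meta$period_px),
    if (is.null(meta$orientation)) "VERTICAL" else meta$orientation)
}
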