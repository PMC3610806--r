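# Shared fixtures: all built in code at test time.

pristine_state <- function(serial = "S1", type_id = "T1", ...) {
  endoscope_state(serial = serial, type_id = type_id, ...)
}

# A record with sensible defaults, timestamp offset in days.
rec <- function(serial = "S1", type_id = "T1", day = 0,
                transmission = 80, contrast = 120, moisture = FALSE,
                context = "CLINICAL") {
  measurement_record(serial, type_id,
                     as.POSIXct("2011-07-07 09:00:00", tz = "UTC") +
                       day * 86400,
                     transmission, contrast, moisture, context)
}

# Registry pre-loaded with records; `...` are endo_records.
reg_with <- function(...) {
  reg <- endo_registry()
  for (r in list(...)) add_record(reg, r)
  reg
}

# Deterministic ROI covering the whole (small) image except corners: a
# disc centred in an n x n image.
full_roi <- function(n) {
  structure(list(center = c((n + 1) / 2, (n + 1) / 2), radius = n / 2),
            class = "endo_roi")
}

# Fill the pixels of a disc ROI with prescribed grey values: `values` is a
# vector recycled over the ROI pixels in column-major order; outside the
# disc the image is 0.
image_with_roi_values <- function(n, roi, values) {
  img <- matrix(0L, n, n)
  d2 <- outer((seq_len(n) - roi$center[1])^2,
              (seq_len(n) - roi$center[2])^2, `+`)
  idx <- which(d2 <= roi$radius^2)
  img[idx] <- as.integer(rep_len(values, length(idx)))
  img
}

# Independent brute-force oracle for the contrast statistic: sort the ROI
# pixels and difference the order statistics at ranks ceil(.25N), ceil(.75N).
contrast_oracle <- function(image, roi) {
  n <- nrow(image); m <- ncol(image)
  d2 <- outer((seq_len(n) - roi$center[1])^2,
              (seq_len(m) - roi$center[2])^2, `+`)
  v <- sort(image[d2 <= roi$radius^2])
  N <- length(v)
  v[ceiling(0.75 * N)] - v[ceiling(0.25 * N)]
}

# Reference-endoscope record series: constant true transmission plus
# relative measurement noise, one record per session.
reference_series <- function(n = 20, noise_sd = 0.01, seed = 1,
                             true_units = 100) {
  st <- pristine_state("REF", "REFERENCE")
  vals <- vapply(seq_len(n), function(i) {
    r <- simulate_transmission_measurement(st, seed = seed * 1000 + i,
                                           noise_sd = noise_sd)
    compute_transmission(r)$units * true_units / 100
  }, numeric(1))
  data.frame(serial = "REF", type_id = "REFERENCE",
             timestamp = as.POSIXct("2011-07-07", tz = "UTC") +
               (seq_len(n) - 1) * 3.5 * 86400,
             transmission = vals, contrast = 120, moisture = FALSE,
             context = "REFERENCE", stringsAsFactors = FALSE)
}
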