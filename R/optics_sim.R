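# Virtual endoscope: a parameterised optical state, an image-formation
# pipeline standing in for the camera-on-eyepiece capture, a photocell
# transmission simulator, and aging/repair dynamics over sterilization
# cycles.

REPAIR_KINDS <- c("CLEAN_DUST", "REPLACE_ROD_LENS", "REPLACE_SAPPHIRE_WINDOW",
                  "REPLACE_OBJECTIVE", "FIX_MOISTURE", "REFIT_EYEPIECE",
                  "REPLACE_FIBRES")

#' Construct a virtual endoscope state
#'
#' Ground truth for the simulator. Degradations map onto the defect classes
#' seen by repair firms: blurred optics (broken rod lenses, damaged
#' objective), veiling glare (internal moisture haze), vignetting
#' (misaligned eyepiece), dust discs on lens surfaces, and low illumination
#' fibre transmission.
#'
#' @param serial opaque endoscope identifier.
#' @param type_id opaque model/type identifier.
#' @param blur_sigma Gaussian point-spread width in sensor pixels, >= 0.
#' @param veiling_glare haze fraction in `[0,1]`; 1 means the image is fully
#'   replaced by a uniform veil.
#' @param vignetting edge-darkening strength in `[0,1]` (quadratic radial
#'   fall-off multiplier `1 - v*(r/rmax)^2`).
#' @param dust list of dust discs, each `list(center=c(row,col), radius_px,
#'   opacity)` with opacity in `[0,1]`.
#' @param fibre_transmission illumination-pathway efficiency in `[0,1]`.
#' @param moisture logical; condensation observed (recorded flag, also
#'   typically accompanied by glare).
#' @param degradation_rates per-sterilization-cycle rates:
#'   `transmission` (multiplicative decay `(1-r)` per cycle), `blur` and
#'   `glare` (additive growth per cycle).
#' @return an `endo_state` object. Factory values of the optical parameters
#'   are recorded at construction for use by [repair_endoscope()].
#' @export
endoscope_state <- function(serial, type_id,
                            blur_sigma = 0, veiling_glare = 0,
                            vignetting = 0, dust = list(),
                            fibre_transmission = 1, moisture = FALSE,
                            degradation_rates = list(transmission = 0,
                                                     blur = 0, glare = 0)) {
  stopifnot_scalar_number(blur_sigma, "blur_sigma", min = 0)
  stopifnot_scalar_number(veiling_glare, "veiling_glare", min = 0, max = 1)
  stopifnot_scalar_number(vignetting, "vignetting", min = 0, max = 1)
  stopifnot_scalar_number(fibre_transmission, "fibre_transmission",
                          min = 0, max = 1)
  for (d in dust) {
    stopifnot_scalar_number(d$opacity, "dust opacity", min = 0, max = 1)
    stopifnot_scalar_number(d$radius_px, "dust radius_px", min = 0)
  }
  rates <- utils::modifyList(list(transmission = 0, blur = 0, glare = 0),
                             as.list(degradation_rates))
  st <- structure(
    list(serial = as.character(serial), type_id = as.character(type_id),
         blur_sigma = blur_sigma, veiling_glare = veiling_glare,
         vignetting = vignetting, dust = dust,
         fibre_transmission = fibre_transmission,
         moisture = isTRUE(moisture), degradation_rates = rates,
         factory = NULL),
    class = "endo_state")
  st$factory <- list(blur_sigma = blur_sigma, veiling_glare = veiling_glare,
                     vignetting = vignetting,
                     fibre_transmission = fibre_transmission)
  st
}

#' @export
print.endo_state <- function(x, ...) {
  cat(sprintf(
    "<endo_state %s (%s): T=%.3f blur=%.2f glare=%.3f vig=%.2f dust=%d%s>\n",
    x$serial, x$type_id, x$fibre_transmission, x$blur_sigma, x$veiling_glare,
    x$vignetting, length(x$dust), if (x$moisture) " MOIST" else ""))
  invisible(x)
}

# Separable Gaussian blur with edge-renormalised truncated kernel,
# implemented as banded matrix products (fast enough in base R for the
# bench's sensor sizes).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  conv_mat <- function(n) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1L & j <= n
      M[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    M
  }
  conv_mat(nrow(img)) %*% img %*% t(conv_mat(ncol(img)))
}

#' Render a test pattern through a virtual endoscope
#'
#' Image-formation stages, in fixed order: (1) circular field mask (black
#' outside the endoscope's image circle); (2) Gaussian blur of width
#' `blur_sigma`; (3) veiling glare, `I' = (1-h) I + h mean(field)` applied
#' inside the mask; (4) radial vignetting `1 - v (r/rmax)^2`; (5) dust
#' discs as multiplicative dark spots; (6) additive Gaussian sensor noise;
#' (7) clip to `[0,255]` and quantize.
#'
#' @param pattern an `endo_pattern`.
#' @param state an `endo_state`.
#' @param seed integer seed for the sensor noise (required when
#'   `noise_sd > 0` for reproducibility; may be NULL for ambient RNG).
#' @param noise_sd sensor noise standard deviation in grey levels.
#' @param field_radius_fraction radius of the endoscope image circle as a
#'   fraction of the half-width.
#' @return integer matrix of captured grey levels 0..255.
#' @export
render_through_endoscope <- function(pattern, state, seed = NULL,
                                     noise_sd = 0,
                                     field_radius_fraction = 0.95) {
  if (!inherits(pattern, "endo_pattern")) {
    abort_endoqc("`pattern` must be an endo_pattern")
  }
  if (!inherits(state, "endo_state")) {
    abort_endoqc("`state` must be an endo_state")
  }
  px <- pattern$pixels
  if (nrow(px) != ncol(px)) {
    abort_endoqc("pattern must be square to match the sensor")
  }
  n <- nrow(px)
  ctr <- (n + 1) / 2
  rmax <- field_radius_fraction * n / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  mask <- d2 <= rmax^2

  img <- as.numeric(px)
  dim(img) <- dim(px)
  img[!mask] <- 0                                   # (1) field mask
  img <- gaussian_blur(img, state$blur_sigma)       # (2) blur
  h <- state$veiling_glare                          # (3) veiling glare
  if (h > 0) {
    field_mean <- mean(img[mask])
    img[mask] <- (1 - h) * img[mask] + h * field_mean
  }
  if (state$vignetting > 0) {                       # (4) vignetting
    img <- img * (1 - state$vignetting * d2 / rmax^2)
  }
  for (d in state$dust) {                           # (5) dust discs
    dd2 <- outer((seq_len(n) - d$center[1])^2,
                 (seq_len(n) - d$center[2])^2, `+`)
    img[dd2 <= d$radius_px^2] <- img[dd2 <= d$radius_px^2] * (1 - d$opacity)
  }
  if (noise_sd > 0) {                               # (6) sensor noise
    img <- img + with_seed(seed, stats::rnorm(length(img), 0, noise_sd))
  }
  matrix(pmin(pmax(as.integer(round(img)), 0L), 255L), n, n)  # (7)
}

new_photocell_reading <- function(calibration_signal, endoscope_signal,
                                  noise_sd = 0) {
  structure(list(calibration_signal = calibration_signal,
                 endoscope_signal = endoscope_signal,
                 noise_sd = noise_sd),
            class = "endo_reading")
}

#' Simulate a photocell transmission measurement
#'
#' Mimics the bench procedure: first the light source is placed directly on
#' the photocell (calibration signal, the 100-unit full scale), then light
#' is sent through the endoscope's illumination fibres and picked up at the
#' distal end.
#'
#' @param state an `endo_state`.
#' @param seed integer seed for the multiplicative reading noise.
#' @param noise_sd relative (fractional) noise standard deviation, >= 0.
#' @param source_level nominal source signal in arbitrary linear units.
#' @return an `endo_reading` with `calibration_signal` and
#'   `endoscope_signal` (floored at 0).
#' @export
simulate_transmission_measurement <- function(state, seed = NULL,
                                              noise_sd = 0,
                                              source_level = 2.5) {
  if (!inherits(state, "endo_state")) {
    abort_endoqc("`state` must be an endo_state")
  }
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  eps <- if (noise_sd > 0) with_seed(seed, stats::rnorm(1, 0, noise_sd)) else 0
  sig <- max(0, source_level * state$fibre_transmission * (1 + eps))
  new_photocell_reading(source_level, sig, noise_sd)
}

#' Age an endoscope over sterilization cycles
#'
#' Per cycle, fibre transmission decays multiplicatively by `(1 - r_T)`,
#' blur grows additively by `r_B`, and veiling glare by `r_G` (clamped at
#' 1). Aging is compositional: `age(age(s,a),b) == age(s,a+b)`.
#'
#' @param state an `endo_state` (not mutated).
#' @param n_cycles number of wash/autoclave cycles, >= 0.
#' @return the aged `endo_state`.
#' @export
age_endoscope <- function(state, n_cycles) {
  if (!inherits(state, "endo_state")) {
    abort_endoqc("`state` must be an endo_state")
  }
  stopifnot_scalar_number(n_cycles, "n_cycles", min = 0, integer = TRUE)
  r <- state$degradation_rates
  state$fibre_transmission <-
    state$fibre_transmission * (1 - r$transmission)^n_cycles
  state$blur_sigma <- state$blur_sigma + n_cycles * r$blur
  state$veiling_glare <- min(1, state$veiling_glare + n_cycles * r$glare)
  state
}

#' Repair a virtual endoscope
#'
#' Each repair restores its mapped optical parameters toward factory value
#' by a restore factor `f` drawn once per call from
#' `uniform(restore_range)`: "lower is better" parameters (blur, glare,
#' vignetting) go to `factory / f` (slightly worse than factory for f < 1)
#' and fibre transmission goes to `factory * f`. Repaired instruments thus
#' sit somewhat below comparable new ones.
#'
#' Mapping: `CLEAN_DUST` empties the dust list; `REPLACE_ROD_LENS` restores
#' blur; `REPLACE_SAPPHIRE_WINDOW` restores blur and glare;
#' `REPLACE_OBJECTIVE` restores blur and vignetting; `FIX_MOISTURE` clears
#' the moisture flag and restores glare; `REFIT_EYEPIECE` restores
#' vignetting; `REPLACE_FIBRES` restores fibre transmission.
#'
#' @param state an `endo_state` (not mutated).
#' @param repairs non-empty character vector of repair kinds.
#' @param seed integer seed for the restore factor.
#' @param restore_range range of the restore factor `f`, default
#'   `c(0.9, 1)`.
#' @return the repaired `endo_state`.
#' @export
repair_endoscope <- function(state, repairs, seed = NULL,
                             restore_range = c(0.9, 1)) {
  if (!inherits(state, "endo_state")) {
    abort_endoqc("`state` must be an endo_state")
  }
  if (length(repairs) == 0L) abort_endoqc("`repairs` must be non-empty")
  repairs <- unique(match.arg(repairs, REPAIR_KINDS, several.ok = TRUE))
  f <- with_seed(seed, stats::runif(1, restore_range[1], restore_range[2]))
  fac <- state$factory
  restore_low <- function(value) value / f          # blur/glare/vignetting
  for (rep in repairs) {
    switch(rep,
      CLEAN_DUST = { state$dust <- list() },
      REPLACE_ROD_LENS = { state$blur_sigma <- restore_low(fac$blur_sigma) },
      REPLACE_SAPPHIRE_WINDOW = {
        state$blur_sigma <- restore_low(fac$blur_sigma)
        state$veiling_glare <- min(1, restore_low(fac$veiling_glare))
      },
      REPLACE_OBJECTIVE = {
        state$blur_sigma <- restore_low(fac$blur_sigma)
        state$vignetting <- min(1, restore_low(fac$vignetting))
      },
      FIX_MOISTURE = {
        state$moisture <- FALSE
        state$veiling_glare <- min(1, restore_low(fac$veiling_glare))
      },
      REFIT_EYEPIECE = {
        state$vignetting <- min(1, restore_low(fac$vignetting))
      },
      REPLACE_FIBRES = {
        state$fibre_transmission <- min(1, fac$fibre_transmission * f)
      })
  }
  state
}
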