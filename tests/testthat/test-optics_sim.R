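test_that("pristine state renders the masked input exactly", {
  p <- generate_line_pattern(1, 128)
  cap <- render_through_endoscope(p, pristine_state())
  n <- 128; ctr <- (n + 1) / 2; rmax <- 0.95 * n / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  expected <- p$pixels
  expected[d2 > rmax^2] <- 0L
  expect_identical(cap, expected)
})

test_that("full veiling glare yields a uniform field inside the mask", {
  p <- generate_line_pattern(0, 128)
  cap <- render_through_endoscope(p, pristine_state(veiling_glare = 1))
  n <- 128; d2 <- outer((seq_len(n) - 64.5)^2, (seq_len(n) - 64.5)^2, `+`)
  inside <- cap[d2 <= (0.95 * 64)^2]
  expect_length(unique(inside), 1L)
  expect_identical(unique(cap[d2 > (0.95 * 64)^2]), 0L)
})

test_that("vignetting darkens the edge, not the centre", {
  p <- new_pattern <- generate_roi_pattern(128, 1)  # bright to the edge
  base <- render_through_endoscope(p, pristine_state())
  vig <- render_through_endoscope(p, pristine_state(vignetting = 0.5))
  expect_identical(vig[64, 64], base[64, 64])
  edge <- which(base == 255L & row(base) == 64)
  expect_true(all(vig[edge] <= base[edge]))
  expect_lt(vig[64, max(which(base[64, ] == 255L))], 255L)
  # vignetting = 0 is identical to the stage being absent
  expect_identical(render_through_endoscope(p, pristine_state(vignetting = 0)),
                   base)
})

test_that("dust discs multiply down the covered pixels only", {
  p <- generate_roi_pattern(64, 1)
  dust <- list(list(center = c(32, 32), radius_px = 5, opacity = 0.5))
  cap <- render_through_endoscope(p, pristine_state(dust = dust))
  base <- render_through_endoscope(p, pristine_state())
  expect_identical(cap[32, 32], as.integer(round(255 * 0.5)))
  expect_identical(cap[10, 32], base[10, 32])
})

test_that("sensor noise is seeded and deterministic", {
  p <- generate_line_pattern(2, 64)
  a <- render_through_endoscope(p, pristine_state(), seed = 11, noise_sd = 2)
  b <- render_through_endoscope(p, pristine_state(), seed = 11, noise_sd = 2)
  c <- render_through_endoscope(p, pristine_state(), seed = 12, noise_sd = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(a >= 0L & a <= 255L))
})

test_that("transmission simulation is exact at zero noise and unbiased", {
  s1 <- pristine_state(fibre_transmission = 1)
  r1 <- simulate_transmission_measurement(s1, noise_sd = 0)
  expect_identical(r1$endoscope_signal, r1$calibration_signal)
  s2 <- pristine_state(fibre_transmission = 0.5)
  r2 <- simulate_transmission_measurement(s2, noise_sd = 0)
  expect_equal(r2$endoscope_signal, 0.5 * r2$calibration_signal)
  # Monte-Carlo mean over 1000 seeded draws recovers the parameter
  s3 <- pristine_state(fibre_transmission = 0.7)
  ratios <- vapply(1:1000, function(i) {
    r <- simulate_transmission_measurement(s3, seed = i, noise_sd = 0.01)
    r$endoscope_signal / r$calibration_signal
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.700), 0.001)
})

test_that("aging follows the closed form and composes", {
  s <- pristine_state(fibre_transmission = 0.8, blur_sigma = 0.5,
                      degradation_rates = list(transmission = 0.01,
                                               blur = 0.02, glare = 0.001))
  expect_identical(age_endoscope(s, 0), s)
  aged <- age_endoscope(s, 10)
  expect_equal(aged$fibre_transmission, 0.8 * 0.99^10)
  expect_equal(aged$blur_sigma, 0.5 + 10 * 0.02)
  expect_equal(aged$veiling_glare, 0.01)
  expect_error(age_endoscope(s, -1), class = "endoqc_invalid_argument")
  # compositionality over random states
  set.seed(42)
  for (i in 1:20) {
    st <- pristine_state(
      fibre_transmission = runif(1, 0.3, 1),
      blur_sigma = runif(1, 0, 2), veiling_glare = runif(1, 0, 0.9),
      degradation_rates = list(transmission = runif(1, 0, 0.05),
                               blur = runif(1, 0, 0.05),
                               glare = runif(1, 0, 0.2)))
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    expect_equal(age_endoscope(age_endoscope(st, a), b),
                 age_endoscope(st, a + b))
  }
})

test_that("repairs restore their mapped parameters toward factory", {
  dust3 <- list(list(center = c(5, 5), radius_px = 2, opacity = 0.5),
                list(center = c(9, 9), radius_px = 1, opacity = 0.2),
                list(center = c(2, 8), radius_px = 1, opacity = 0.9))
  s <- age_endoscope(endoscope_state(
    "S1", "T1", blur_sigma = 0.5, fibre_transmission = 0.9,
    dust = dust3, moisture = TRUE,
    degradation_rates = list(transmission = 0.01, blur = 0.05)), 20)

  cleaned <- repair_endoscope(s, "CLEAN_DUST")
  expect_length(cleaned$dust, 0L)
  expect_equal(cleaned$blur_sigma, s$blur_sigma)  # other fields unchanged
  fixed <- repair_endoscope(s, "FIX_MOISTURE", seed = 1)
  expect_false(fixed$moisture)

  # restore factor is the independently evaluated seeded uniform draw
  f <- withr::with_seed(99, runif(1, 0.9, 1))
  lens <- repair_endoscope(s, "REPLACE_ROD_LENS", seed = 99)
  expect_equal(lens$blur_sigma, 0.5 / f)
  expect_equal(lens$fibre_transmission, s$fibre_transmission)  # untouched
  fib <- repair_endoscope(s, "REPLACE_FIBRES", seed = 99)
  expect_equal(fib$fibre_transmission, 0.9 * f)
  expect_error(repair_endoscope(s, character()),
               class = "endoqc_invalid_argument")
})

test_that("fleet history is deterministic and shows the stated world", {
  cfg <- fleet_config(seed = 7, n_types = 2, endoscopes_per_type = 3,
                      n_sessions = 20)
  h1 <- simulate_fleet_history(cfg)
  h2 <- simulate_fleet_history(cfg)
  expect_identical(h1, h2)

  # the reference endoscope's ground truth never changes
  ref <- Filter(function(e) e$serial == "REF-0", h1$entries)
  expect_length(ref, 20L)
  expect_true(all(vapply(ref, function(e)
    identical(e$state, ref[[1]]$state), logical(1))))

  # at least one clinical endoscope strictly loses transmission
  serials <- setdiff(unique(vapply(h1$entries, `[[`, character(1),
                                   "serial")), "REF-0")
  drops <- vapply(serials, function(s) {
    tr <- vapply(Filter(function(e) e$serial == s, h1$entries),
                 function(e) e$state$fibre_transmission, numeric(1))
    all(diff(tr) < 0)
  }, logical(1))
  expect_true(any(drops))

  # repairs raise quality above where they left it
  befores <- Filter(function(e) e$context == "BEFORE_REPAIR", h1$entries)
  afters <- Filter(function(e) e$context == "AFTER_REPAIR", h1$entries)
  expect_gt(length(befores), 0L)
  expect_identical(length(befores), length(afters))
  for (i in seq_along(befores)) {
    expect_gt(afters[[i]]$state$fibre_transmission,
              befores[[i]]$state$fibre_transmission)
  }
})
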