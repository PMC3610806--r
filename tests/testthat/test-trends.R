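series_df <- function(values, days = seq_along(values) - 1,
                      serial = "S1") {
  data.frame(serial = serial, type_id = "T1",
             timestamp = as.POSIXct("2011-07-07", tz = "UTC") +
               days * 86400,
             transmission = values, contrast = values, moisture = FALSE,
             context = "CLINICAL", stringsAsFactors = FALSE)
}

test_that("stability_report counts band fractions by brute force", {
  sr <- stability_report(series_df(c(98, 100, 102, 100)), "TRANSMISSION",
                         bands = 2)
  expect_equal(unname(sr$fraction_within), 1.0)  # all within 2% of mean 100
  # constant series: everything within any band, zero slope, no drift
  sc <- stability_report(series_df(rep(77, 10)), "TRANSMISSION",
                         bands = c(2, 3))
  expect_equal(unname(sc$fraction_within), c(1, 1))
  expect_equal(sc$drift_slope, 0)
  expect_false(sc$drift_significant)
  # fractions are non-decreasing in band and match direct counting
  set.seed(17)
  vals <- 100 * (1 + rnorm(40, 0, 0.02))
  sr2 <- stability_report(series_df(vals), "TRANSMISSION", bands = c(1, 2, 5))
  expect_true(!is.unsorted(sr2$fraction_within))
  mu <- mean(vals)
  for (b in c(1, 2, 5)) {
    expect_equal(unname(sr2$fraction_within[paste0(b, "%")]),
                 mean(abs(vals - mu) / mu <= b / 100))
  }
  expect_error(stability_report(series_df(c(1, 2))),
               class = "endoqc_insufficient_data")
})

test_that("drift test recovers a constructed linear decline", {
  days <- seq(0, 70, by = 3.5)
  vals <- 100 - 0.25 * days + withr::with_seed(9, rnorm(length(days), 0, 0.3))
  sr <- stability_report(series_df(vals, days), "TRANSMISSION")
  expect_true(sr$drift_significant)
  expect_equal(sr$drift_slope, -0.25, tolerance = 0.05)
  # noiseless linear data: slope exact to numerical precision
  tr <- trend(series_df(100 - 0.25 * days, days), "TRANSMISSION")
  expect_equal(tr$slope, -0.25, tolerance = 1e-12)
})

test_that("trend reports endpoint change and rejection crossing", {
  flat <- trend(series_df(rep(90, 5)), "TRANSMISSION",
                bests = c(TRANSMISSION = 100, CONTRAST = 100))
  expect_equal(flat$slope, 0)
  expect_false(flat$crossed_rejection)
  falling <- series_df(c(60, 50, 40, 30, 19, 15))
  tr <- trend(falling, "TRANSMISSION",
              bests = c(TRANSMISSION = 100, CONTRAST = 100))
  expect_true(tr$crossed_rejection)
  expect_identical(tr$crossing_date, falling$timestamp[5])  # first < 20
  expect_true(tr$endpoint_significant)
  expect_error(trend(series_df(c(1, 2))),
               class = "endoqc_insufficient_data")
})

test_that("rejection crossing matches the simulator's ground truth", {
  cfg <- fleet_config(seed = 21, n_types = 1, endoscopes_per_type = 3,
                      n_sessions = 16, n_fast_decayers_per_type = 1)
  h <- simulate_fleet_history(cfg)
  fast <- Filter(function(e) e$serial == "TYPE-01-S01", h$entries)
  gt <- vapply(fast, function(e) e$state$fibre_transmission, numeric(1))
  best0 <- max(vapply(Filter(function(e) e$session == 1 &&
                               e$type_id == "TYPE-01", h$entries),
                      function(e) e$state$fibre_transmission, numeric(1)))
  # noiseless measured series = 100 * ground truth; baseline = 100 * best
  recs <- series_df(100 * gt,
                    days = (vapply(fast, `[[`, numeric(1), "session") - 1) *
                      3.5, serial = "TYPE-01-S01")
  tr <- trend(recs, "TRANSMISSION",
              bests = c(TRANSMISSION = 100 * best0, CONTRAST = 100))
  gt_below <- which(gt < 0.2 * best0)
  expect_identical(tr$crossed_rejection, length(gt_below) > 0)
  if (length(gt_below)) {
    expect_identical(tr$crossing_date, recs$timestamp[gt_below[1]])
  }
})

test_that("repair_effect applies the shared 5% rule", {
  b <- rec(day = 0, transmission = 50, contrast = 50,
           context = "BEFORE_REPAIR")
  a20 <- rec(day = 1, transmission = 60, contrast = 51,
             context = "AFTER_REPAIR")
  eff <- repair_effect(b, a20, metric = "TRANSMISSION")
  expect_identical(eff$classification, "IMPROVED")
  expect_identical(repair_effect(b, a20, metric = "CONTRAST")$classification,
                   "UNCHANGED")  # +2%
  worse <- rec(day = 1, transmission = 40, contrast = 50,
               context = "AFTER_REPAIR")
  expect_identical(repair_effect(b, worse)$classification, "WORSENED")
  expect_error(repair_effect(b, rec(serial = "S2", day = 1,
                                    context = "AFTER_REPAIR")),
               class = "endoqc_invalid_argument")
  expect_error(repair_effect(b, rec(day = 1, context = "CLINICAL")),
               class = "endoqc_invalid_argument")
  # single source of truth: agrees with significant_change on random pairs
  set.seed(13)
  for (i in 1:30) {
    tb <- runif(1, 20, 100); ta <- tb * runif(1, 0.8, 1.3)
    e <- repair_effect(rec(day = 0, transmission = tb,
                           context = "BEFORE_REPAIR"),
                       rec(day = 1, transmission = ta,
                           context = "AFTER_REPAIR"))
    ch <- significant_change(tb, ta)
    expect_identical(e$classification != "UNCHANGED", ch$significant)
  }
})

test_that("a constructed 14-pair repair cohort is classified 9/5", {
  # 9 transmission improvements > 5%, 5 within +/-5%, by construction
  set.seed(41)
  gains <- c(runif(9, 1.06, 1.5), runif(5, 0.953, 1.049))
  cls <- vapply(seq_along(gains), function(i) {
    before <- runif(1, 30, 80)
    repair_effect(
      rec(serial = paste0("E", i), day = 0, transmission = before,
          context = "BEFORE_REPAIR"),
      rec(serial = paste0("E", i), day = 1,
          transmission = before * gains[i], context = "AFTER_REPAIR")
    )$classification
  }, character(1))
  expect_identical(as.vector(table(factor(cls, c("IMPROVED", "UNCHANGED",
                                                 "WORSENED")))),
                   c(9L, 5L, 0L))
})
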