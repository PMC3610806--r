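# Longitudinal analyses: reference-endoscope stability, per-endoscope
# trends, and before/after-repair comparisons. Drift and trend tests are
# ordinary least squares against days since the first record, with a
# two-sided t-test on the slope at level 0.05.

ols_slope <- function(days, values) {
  fit <- stats::lm(values ~ days)
  sm <- suppressWarnings(summary(fit))$coefficients
  if (nrow(sm) < 2L || is.na(sm[2L, 2L])) {
    # degenerate design (e.g. zero residual variance): slope exact, no test
    list(slope = unname(stats::coef(fit)[2L]), se = 0, p = NA_real_)
  } else {
    list(slope = sm[2L, 1L], se = sm[2L, 2L], p = sm[2L, 4L])
  }
}

records_series <- function(records, metric) {
  metric <- match.arg(metric, METRICS)
  if (!is.data.frame(records) || nrow(records) < 3L) {
    abort_endoqc("need at least 3 records", "endoqc_insufficient_data")
  }
  records <- records[order(records$timestamp), , drop = FALSE]
  list(
    days = as.numeric(difftime(records$timestamp, records$timestamp[1L],
                               units = "days")),
    values = records[[if (metric == "TRANSMISSION") "transmission"
                      else "contrast"]],
    records = records, metric = metric)
}

#' Stability report for the reference endoscope
#'
#' The reference endoscope is never used clinically; it is measured once
#' per session purely to verify that the bench itself is stable. The
#' report gives the series mean, the fraction of points within each
#' relative band of the mean (e.g. 95% within 2% for transmission), and an
#' OLS drift test.
#'
#' @param reference_records data frame of records (as returned by
#'   [query_by_serial()]), >= 3 rows.
#' @param metric `"TRANSMISSION"` or `"CONTRAST"`.
#' @param bands relative bands in percent, default `c(2, 3)`.
#' @param level significance level for the drift t-test.
#' @return a `stability_report` list: `metric`, `mean`, `fraction_within`
#'   (named by band), `drift_slope`, `drift_se`, `drift_p`,
#'   `drift_significant`.
#' @export
stability_report <- function(reference_records, metric = "TRANSMISSION",
                             bands = c(2, 3), level = 0.05) {
  s <- records_series(reference_records, metric)
  mu <- mean(s$values)
  frac <- vapply(sort(bands), function(b) {
    mean(abs(s$values - mu) / mu <= b / 100)
  }, numeric(1))
  names(frac) <- paste0(sort(bands), "%")
  dr <- ols_slope(s$days, s$values)
  structure(list(metric = s$metric, mean = mu, n = length(s$values),
                 fraction_within = frac,
                 drift_slope = dr$slope, drift_se = dr$se, drift_p = dr$p,
                 drift_significant = !is.na(dr$p) && dr$p < level),
            class = "stability_report")
}

#' Performance trend for one endoscope
#'
#' OLS slope of the metric against days since first measurement, the
#' endpoint relative change classified by the 5% significance rule, and —
#' when a best-of-type baseline is supplied — the first date at which a
#' pointwise rejection decision fires.
#'
#' @param records data frame of one serial's records, >= 3 rows.
#' @param metric `"TRANSMISSION"` or `"CONTRAST"`.
#' @param bests optional named numeric `c(TRANSMISSION=, CONTRAST=)` for
#'   rejection crossing.
#' @param config a [qa_config()].
#' @param level significance level for the slope t-test.
#' @return a `trend_report` list: `serial`, `metric`, `slope` (units/day),
#'   `se`, `p`, `drift_significant`, `endpoint_change` (percent),
#'   `endpoint_significant`, `crossed_rejection`, `crossing_date`.
#' @export
trend <- function(records, metric = "TRANSMISSION", bests = NULL,
                  config = qa_config(), level = 0.05) {
  s <- records_series(records, metric)
  dr <- ols_slope(s$days, s$values)
  ec <- significant_change(s$values[1L], s$values[length(s$values)], config)
  crossed <- FALSE
  crossing_date <- as.POSIXct(NA, tz = "UTC")
  if (!is.null(bests)) {
    level_val <- config$rejection_fraction * bests[[s$metric]]
    below <- which(s$values < level_val)
    if (length(below)) {
      crossed <- TRUE
      crossing_date <- s$records$timestamp[below[1L]]
    }
  }
  structure(list(serial = s$records$serial[1L], metric = s$metric,
                 slope = dr$slope, se = dr$se, p = dr$p,
                 drift_significant = !is.na(dr$p) && dr$p < level,
                 endpoint_change = ec$relative_change,
                 endpoint_significant = ec$significant,
                 crossed_rejection = crossed, crossing_date = crossing_date),
            class = "trend_report")
}

#' Effect of a repair on one metric
#'
#' Classifies the before/after change with the same 5% rule as
#' [significant_change()] (single source of truth): IMPROVED above +5%,
#' WORSENED below -5%, otherwise UNCHANGED.
#'
#' @param before,after `endo_record`s for the same serial, with contexts
#'   BEFORE_REPAIR and AFTER_REPAIR.
#' @param config a [qa_config()].
#' @param metric `"TRANSMISSION"` or `"CONTRAST"`.
#' @return a `repair_effect` list: `serial`, `metric`, `before`, `after`,
#'   `relative_change`, `classification`.
#' @export
repair_effect <- function(before, after, config = qa_config(),
                          metric = "TRANSMISSION") {
  metric <- match.arg(metric, METRICS)
  if (!identical(before$serial, after$serial)) {
    abort_endoqc("before/after records must share the same serial")
  }
  if (before$context != "BEFORE_REPAIR" || after$context != "AFTER_REPAIR") {
    abort_endoqc("contexts must be BEFORE_REPAIR and AFTER_REPAIR")
  }
  field <- if (metric == "TRANSMISSION") "transmission" else "contrast"
  ch <- significant_change(before[[field]], after[[field]], config)
  cls <- if (!ch$significant) "UNCHANGED"
         else if (ch$relative_change > 0) "IMPROVED" else "WORSENED"
  structure(list(serial = before$serial, metric = metric,
                 before = before[[field]], after = after[[field]],
                 relative_change = ch$relative_change,
                 classification = cls),
            class = "repair_effect")
}
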