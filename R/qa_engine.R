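# Decision logic: acceptance of new/repaired endoscopes at 40% of the
# best-of-type baseline, rejection of clinical endoscopes below 20%, and
# the 5% significance rule for changes between measurements.
#
# Both metrics must clear the acceptance bar independently (AND), and a
# clinical endoscope is rejected if EITHER metric falls below the
# rejection level — conservative readings of "measurement values" plural.

#' QA thresholds
#'
#' @param acceptance_fraction minimum fraction of best-of-type for
#'   accepting NEW/AFTER_REPAIR endoscopes (default 0.40, inclusive:
#'   "at least 40%").
#' @param rejection_fraction fraction of best-of-type below which a
#'   CLINICAL endoscope is rejected (default 0.20, strict-below).
#' @param significance_fraction relative change regarded as significant
#'   when strictly exceeded (default 0.05, from the reference endoscope's
#'   2-3% stability bands).
#' @return a `qa_config`.
#' @export
qa_config <- function(acceptance_fraction = 0.40, rejection_fraction = 0.20,
                      significance_fraction = 0.05) {
  stopifnot_scalar_number(significance_fraction, "significance_fraction")
  if (significance_fraction <= 0) {
    abort_endoqc("`significance_fraction` must be > 0")
  }
  if (!(rejection_fraction > 0 && rejection_fraction < acceptance_fraction &&
        acceptance_fraction <= 1)) {
    abort_endoqc("need 0 < rejection_fraction < acceptance_fraction <= 1")
  }
  structure(list(acceptance_fraction = acceptance_fraction,
                 rejection_fraction = rejection_fraction,
                 significance_fraction = significance_fraction),
            class = "qa_config")
}

#' Relative performance against the best-of-type baseline
#'
#' @param value measured metric value.
#' @param best best-of-type value (the 100% reference level), > 0.
#' @return percent of best-of-type.
#' @export
relative_performance <- function(value, best) {
  if (!is.numeric(best) || length(best) != 1L || is.na(best) || best <= 0) {
    abort_endoqc("baseline must be a positive number", "endoqc_no_baseline")
  }
  100 * value / best
}

new_decision <- function(verdict, per_metric_relative, triggered_rules,
                         moisture_flagged) {
  structure(list(verdict = verdict,
                 per_metric_relative = per_metric_relative,
                 triggered_rules = triggered_rules,
                 moisture_flagged = moisture_flagged),
            class = "endo_decision")
}

#' @export
print.endo_decision <- function(x, ...) {
  cat(sprintf("<decision %s: T=%.1f%% C=%.1f%%%s%s>\n", x$verdict,
              x$per_metric_relative[["TRANSMISSION"]],
              x$per_metric_relative[["CONTRAST"]],
              if (length(x$triggered_rules))
                paste0(" [", paste(x$triggered_rules, collapse = ", "), "]")
              else "",
              if (x$moisture_flagged) " MOISTURE" else ""))
  invisible(x)
}

rel_perf_both <- function(record, bests) {
  c(TRANSMISSION = relative_performance(record$transmission,
                                        bests[["TRANSMISSION"]]),
    CONTRAST = relative_performance(record$contrast, bests[["CONTRAST"]]))
}

#' Acceptance decision for a new or repaired endoscope
#'
#' ACCEPT iff BOTH transmission and contrast are at least
#' `100 * acceptance_fraction` percent of their best-of-type baselines
#' (boundary inclusive); otherwise REJECT, with each failing metric named
#' in `triggered_rules`.
#'
#' @param record an `endo_record` with context NEW or AFTER_REPAIR.
#' @param bests named numeric, `c(TRANSMISSION=, CONTRAST=)`.
#' @param config a [qa_config()].
#' @return an `endo_decision`.
#' @export
decide_acceptance <- function(record, bests, config = qa_config()) {
  if (!record$context %in% c("NEW", "AFTER_REPAIR")) {
    abort_endoqc(sprintf(
      "acceptance applies to NEW/AFTER_REPAIR records, got %s",
      record$context))
  }
  rel <- rel_perf_both(record, bests)
  level <- 100 * config$acceptance_fraction
  failing <- names(rel)[rel < level]
  rules <- sprintf("%s-below-acceptance", tolower(failing))
  new_decision(if (length(failing)) "REJECT" else "ACCEPT",
               rel, rules, isTRUE(record$moisture))
}

#' Rejection decision for a clinically used endoscope
#'
#' REJECT iff EITHER metric falls strictly below
#' `100 * rejection_fraction` percent of best-of-type; otherwise PASS.
#' Moisture is reported via `moisture_flagged` but never forces rejection
#' on its own.
#'
#' @param record an `endo_record` with context CLINICAL.
#' @param bests named numeric, `c(TRANSMISSION=, CONTRAST=)`.
#' @param config a [qa_config()].
#' @return an `endo_decision`.
#' @export
decide_rejection <- function(record, bests, config = qa_config()) {
  if (record$context != "CLINICAL") {
    abort_endoqc(sprintf("rejection applies to CLINICAL records, got %s",
                         record$context))
  }
  rel <- rel_perf_both(record, bests)
  level <- 100 * config$rejection_fraction
  failing <- names(rel)[rel < level]
  rules <- sprintf("%s-below-rejection", tolower(failing))
  new_decision(if (length(failing)) "REJECT" else "PASS",
               rel, rules, isTRUE(record$moisture))
}

#' Is a change between two measurements significant?
#'
#' Relative change is `100 * (current - previous) / previous` percent;
#' significant iff its absolute value strictly exceeds
#' `100 * significance_fraction` (differences *larger than* 5% by
#' default).
#'
#' @param previous earlier metric value, > 0.
#' @param current later metric value.
#' @param config a [qa_config()].
#' @return list with `significant` (logical) and `relative_change`
#'   (signed percent).
#' @export
significant_change <- function(previous, current, config = qa_config()) {
  if (!is.numeric(previous) || length(previous) != 1L || is.na(previous) ||
      previous <= 0) {
    abort_endoqc("`previous` must be > 0")
  }
  rel <- 100 * (current - previous) / previous
  list(significant = abs(rel) > 100 * config$significance_fraction,
       relative_change = rel)
}
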