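# Fleet-history simulator: the synthetic stand-in for an eight-month
# measurement campaign. One reference endoscope with zero degradation is
# measured every session; clinical endoscopes age between sessions, are
# sent for repair when their ground-truth transmission falls below the
# rejection level, and decay faster for a burn-in period after repair.

#' Configuration for a synthetic fleet history
#'
#' Defaults emulate the study design this bench was run under: twice-weekly
#' sessions over months, a handful of endoscopes per type, slow downward
#' quality trends, a rock-stable reference endoscope (noise only, ~1%
#' relative sd so ~95% of points fall within 2% of the mean), repairs
#' triggered at the 20% rejection level that restore quality above the 40%
#' acceptance level, and accelerated post-repair transmission decay.
#'
#' @param n_types number of endoscope types.
#' @param endoscopes_per_type clinical endoscopes per type.
#' @param n_sessions number of measurement sessions.
#' @param session_interval days between sessions (3.5 = twice weekly).
#' @param cycles_per_session sterilization cycles elapsing between
#'   sessions for a clinical endoscope.
#' @param reference_noise_sd relative sd of the transmission reading noise
#'   (also used for clinical readings).
#' @param capture_noise_sd sensor noise sd in grey levels for rendered
#'   captures.
#' @param transmission_decay_range per-cycle fibre decay rate range; each
#'   endoscope draws its own rate.
#' @param n_fast_decayers_per_type number of endoscopes per type whose
#'   fibre decay rate is drawn from `fast_decay_range` instead — the
#'   low performers that reach the rejection level and get repaired
#'   within the study window.
#' @param fast_decay_range per-cycle fibre decay rate range for the fast
#'   decayers.
#' @param blur_growth_range per-cycle additive blur growth range (px).
#' @param glare_growth_range per-cycle additive glare growth range.
#' @param initial_transmission_range factory fibre transmission range.
#' @param initial_blur_range factory blur sigma range (px).
#' @param repair_trigger_fraction ground-truth transmission fraction of
#'   the type's best factory value below which a repair is triggered.
#' @param restore_range repair restore-factor range (see
#'   [repair_endoscope()]).
#' @param burn_in_factor multiplier on the fibre decay rate right after a
#'   repair.
#' @param burn_in_sessions number of sessions the burn-in lasts.
#' @param image_size sensor/pattern side length used when measuring the
#'   fleet.
#' @param start_date first session date (UTC).
#' @param seed integer master seed; fixed seed implies identical output.
#' @return a `fleet_config`.
#' @export
fleet_config <- function(n_types = 2, endoscopes_per_type = 3,
                         n_sessions = 20, session_interval = 3.5,
                         cycles_per_session = 5,
                         reference_noise_sd = 0.01,
                         capture_noise_sd = 1,
                         transmission_decay_range = c(0.001, 0.004),
                         n_fast_decayers_per_type = 1,
                         fast_decay_range = c(0.016, 0.024),
                         blur_growth_range = c(0.002, 0.008),
                         glare_growth_range = c(0.0002, 0.001),
                         initial_transmission_range = c(0.75, 0.95),
                         initial_blur_range = c(0.3, 0.8),
                         repair_trigger_fraction = 0.2,
                         restore_range = c(0.9, 1),
                         burn_in_factor = 3,
                         burn_in_sessions = 5,
                         image_size = 128,
                         start_date = "2011-07-07T09:00:00Z",
                         seed = 1) {
  for (nm in c("n_types", "endoscopes_per_type", "n_sessions")) {
    stopifnot_scalar_number(get(nm), nm, min = 1, integer = TRUE)
  }
  stopifnot_scalar_number(session_interval, "session_interval", min = 0)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  structure(as.list(environment()), class = "fleet_config")
}

#' Simulate ground-truth fleet history
#'
#' Deterministic given `config$seed`. Produces, per session and per
#' endoscope, the ground-truth `endo_state` at measurement time together
#' with identification, timestamp and context. The reference endoscope
#' ("REF-0", type "REFERENCE") has zero degradation rates and appears in
#' every session; clinical endoscopes enter as NEW in session 1, age
#' between sessions, and when their ground-truth transmission falls below
#' `repair_trigger_fraction` of the best factory transmission of their
#' type they are measured BEFORE_REPAIR, repaired (rod lens + fibres +
#' dust clean), and re-measured AFTER_REPAIR in the same session.
#'
#' @param config a [fleet_config()].
#' @return a `fleet_history`: list with `config`, `sessions` (data frame
#'   of session dates) and `entries`, a list of
#'   `list(session, timestamp, serial, type_id, context, state)` in
#'   chronological order.
#' @export
simulate_fleet_history <- function(config = fleet_config()) {
  if (!inherits(config, "fleet_config")) {
    abort_endoqc("`config` must be a fleet_config")
  }
  cfg <- config
  start <- parse_ts(cfg$start_date)
  if (is.na(start)) start <- as.POSIXct(cfg$start_date, tz = "UTC")
  dates <- start + (seq_len(cfg$n_sessions) - 1) * cfg$session_interval *
    86400

  scopes <- with_seed(cfg$seed, {
    out <- list()
    for (t in seq_len(cfg$n_types)) {
      type_id <- sprintf("TYPE-%02d", t)
      for (k in seq_len(cfg$endoscopes_per_type)) {
        decay_range <- if (k <= cfg$n_fast_decayers_per_type) {
          cfg$fast_decay_range
        } else {
          cfg$transmission_decay_range
        }
        st <- endoscope_state(
          serial = sprintf("%s-S%02d", type_id, k), type_id = type_id,
          blur_sigma = stats::runif(1, cfg$initial_blur_range[1],
                                    cfg$initial_blur_range[2]),
          fibre_transmission = stats::runif(
            1, cfg$initial_transmission_range[1],
            cfg$initial_transmission_range[2]),
          degradation_rates = list(
            transmission = stats::runif(1, decay_range[1],
                                        decay_range[2]),
            blur = stats::runif(1, cfg$blur_growth_range[1],
                                cfg$blur_growth_range[2]),
            glare = stats::runif(1, cfg$glare_growth_range[1],
                                 cfg$glare_growth_range[2])))
        out[[st$serial]] <- st
      }
    }
    out
  })
  base_rates <- lapply(scopes, function(s) s$degradation_rates$transmission)
  best_factory_T <- tapply(
    vapply(scopes, `[[`, numeric(1), "fibre_transmission"),
    vapply(scopes, `[[`, character(1), "type_id"), max)
  reference <- endoscope_state("REF-0", "REFERENCE")
  burn_in_left <- stats::setNames(integer(length(scopes)), names(scopes))

  entries <- list()
  push <- function(session, ts, context, state) {
    entries[[length(entries) + 1L]] <<- list(
      session = session, timestamp = ts, serial = state$serial,
      type_id = state$type_id, context = context, state = state)
  }
  repair_seq <- 0L
  for (s in seq_len(cfg$n_sessions)) {
    push(s, dates[s], "REFERENCE", reference)
    for (serial in names(scopes)) {
      st <- scopes[[serial]]
      if (s > 1L) {
        # burn-in: accelerated fibre decay right after a repair
        rate <- base_rates[[serial]] *
          if (burn_in_left[serial] > 0L) cfg$burn_in_factor else 1
        st$degradation_rates$transmission <- rate
        st <- age_endoscope(st, cfg$cycles_per_session)
        burn_in_left[serial] <- max(0L, burn_in_left[serial] - 1L)
      }
      trigger <- cfg$repair_trigger_fraction *
        best_factory_T[[st$type_id]]
      if (s > 1L && st$fibre_transmission < trigger) {
        push(s, dates[s], "BEFORE_REPAIR", st)
        repair_seq <- repair_seq + 1L
        st <- repair_endoscope(
          st, c("REPLACE_ROD_LENS", "REPLACE_FIBRES", "CLEAN_DUST"),
          seed = derive_seed(cfg$seed, 7000L + repair_seq),
          restore_range = cfg$restore_range)
        burn_in_left[serial] <- as.integer(cfg$burn_in_sessions)
        push(s, dates[s] + 3600, "AFTER_REPAIR", st)
      } else {
        push(s, dates[s], if (s == 1L) "NEW" else "CLINICAL", st)
      }
      scopes[[serial]] <- st
    }
  }
  structure(list(config = cfg,
                 sessions = data.frame(session = seq_len(cfg$n_sessions),
                                       date = dates),
                 entries = entries),
            class = "fleet_history")
}

#' @export
print.fleet_history <- function(x, ...) {
  cat(sprintf("<fleet_history: %d sessions, %d entries, seed %d>\n",
              nrow(x$sessions), length(x$entries), x$config$seed))
  invisible(x)
}

#' Measure a simulated fleet history on the virtual bench
#'
#' Runs the full measurement pipeline for every history entry: simulated
#' photocell reading plus rendered captures of the default pattern suite,
#' fed through [measure_endoscope()]. Per-entry seeds are derived from the
#' config seed, so the output is deterministic.
#'
#' @param history a `fleet_history`.
#' @param registry optional `endo_registry` to store records into (created
#'   if NULL).
#' @return the registry, invisibly gaining one record per entry.
#' @export
measure_fleet <- function(history, registry = NULL) {
  if (!inherits(history, "fleet_history")) {
    abort_endoqc("`history` must be a fleet_history")
  }
  cfg <- history$config
  if (is.null(registry)) registry <- endo_registry()
  suite <- default_pattern_suite(cfg$image_size)
  lines <- suite[1:7]
  roi_pat <- suite[[8]]
  for (i in seq_along(history$entries)) {
    e <- history$entries[[i]]
    sd_cap <- cfg$capture_noise_sd
    captures <- lapply(seq_along(lines), function(j) {
      render_through_endoscope(lines[[j]], e$state,
                               seed = derive_seed(cfg$seed, i * 100L + j),
                               noise_sd = sd_cap)
    })
    roi_cap <- render_through_endoscope(
      roi_pat, e$state, seed = derive_seed(cfg$seed, i * 100L + 99L),
      noise_sd = sd_cap)
    reading <- simulate_transmission_measurement(
      e$state, seed = derive_seed(cfg$seed, 50000L + i),
      noise_sd = cfg$reference_noise_sd)
    rec <- measure_endoscope(captures, roi_cap, reading,
                             moisture_observed = e$state$moisture,
                             serial = e$serial, type_id = e$type_id,
                             timestamp = e$timestamp, context = e$context)
    add_record(registry, rec)
  }
  registry
}
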