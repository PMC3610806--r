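# Measurement registry: a single-table store of bench records keyed by
# endoscope serial and type, with best-of-type baseline lookup and a CSV
# dialect for persistence (header:
# serial,type_id,timestamp,transmission,contrast,moisture,context).

CONTEXTS <- c("CLINICAL", "NEW", "BEFORE_REPAIR", "AFTER_REPAIR", "REFERENCE")
METRICS <- c("TRANSMISSION", "CONTRAST")

#' Construct and validate a measurement record
#'
#' @param serial,type_id opaque identifiers (coerced to character).
#' @param timestamp POSIXct (or ISO-8601 string) measurement time, UTC.
#' @param transmission transmission units, >= 0 (may slightly exceed 100
#'   under noise).
#' @param contrast average contrast in grey levels, 0..255.
#' @param moisture logical cold-spray result.
#' @param context one of CLINICAL, NEW, BEFORE_REPAIR, AFTER_REPAIR,
#'   REFERENCE.
#' @return an `endo_record`.
#' @export
measurement_record <- function(serial, type_id, timestamp, transmission,
                               contrast, moisture = FALSE,
                               context = "CLINICAL") {
  context <- match.arg(context, CONTEXTS)
  stopifnot_scalar_number(transmission, "transmission", min = 0)
  stopifnot_scalar_number(contrast, "contrast", min = 0, max = 255)
  ts <- if (is.character(timestamp)) parse_ts(timestamp)
        else as.POSIXct(timestamp, tz = "UTC")
  if (is.na(ts)) abort_endoqc("invalid timestamp", "endoqc_validation_error")
  structure(list(serial = as.character(serial),
                 type_id = as.character(type_id),
                 timestamp = ts, transmission = transmission,
                 contrast = contrast, moisture = isTRUE(moisture),
                 context = context),
            class = "endo_record")
}

#' Create an empty measurement registry
#'
#' Environment-backed so [add_record()] can append in place, like a
#' database handle.
#'
#' @return an `endo_registry`.
#' @export
endo_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$records <- data.frame(serial = character(), type_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          transmission = numeric(), contrast = numeric(),
                          moisture = logical(), context = character(),
                          stringsAsFactors = FALSE)
  structure(e, class = "endo_registry")
}

#' @export
print.endo_registry <- function(x, ...) {
  cat(sprintf("<endo_registry: %d records, %d serials, %d types>\n",
              nrow(x$records), length(unique(x$records$serial)),
              length(unique(x$records$type_id))))
  invisible(x)
}

#' Store a measurement record
#'
#' Records are keyed by (serial, timestamp); storing a duplicate key is a
#' conflict. Validation is re-run on insert so malformed rows can never
#' enter the store.
#'
#' @param registry an `endo_registry`.
#' @param record an `endo_record` (or a list with the same fields, which
#'   is validated through [measurement_record()]).
#' @return the stored row id, invisibly.
#' @export
add_record <- function(registry, record) {
  if (!inherits(registry, "endo_registry")) {
    abort_endoqc("`registry` must be an endo_registry")
  }
  if (!inherits(record, "endo_record")) {
    record <- tryCatch(
      do.call(measurement_record,
              record[c("serial", "type_id", "timestamp", "transmission",
                       "contrast", "moisture", "context")]),
      error = function(e) {
        abort_endoqc(conditionMessage(e), "endoqc_validation_error")
      })
  }
  df <- registry$records
  dup <- df$serial == record$serial & df$timestamp == record$timestamp
  if (any(dup)) {
    abort_endoqc(sprintf("duplicate record for serial %s at %s",
                         record$serial, format_ts(record$timestamp)),
                 "endoqc_conflict")
  }
  registry$records <- rbind(df, data.frame(
    serial = record$serial, type_id = record$type_id,
    timestamp = record$timestamp, transmission = record$transmission,
    contrast = record$contrast, moisture = record$moisture,
    context = record$context, stringsAsFactors = FALSE))
  invisible(nrow(registry$records))
}

#' Query records for one endoscope, in time order
#'
#' @param registry an `endo_registry`.
#' @param serial endoscope serial number.
#' @param context optional context filter.
#' @return data frame of records in ascending timestamp order (possibly
#'   empty).
#' @export
query_by_serial <- function(registry, serial, context = NULL) {
  df <- registry$records
  sel <- df$serial == as.character(serial)
  if (!is.null(context)) {
    sel <- sel & df$context == match.arg(context, CONTEXTS)
  }
  out <- df[sel, , drop = FALSE]
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-of-type baseline value
#'
#' The 100% reference level: the maximum of a metric over every stored
#' record of the given type, regardless of context (so NEW and
#' AFTER_REPAIR measurements raise the bar). Each metric is maximised
#' independently.
#'
#' @param registry an `endo_registry`.
#' @param type_id endoscope type.
#' @param metric `"TRANSMISSION"` or `"CONTRAST"`.
#' @return best historical value of the metric.
#' @export
best_of_type <- function(registry, type_id, metric) {
  metric <- match.arg(metric, METRICS)
  df <- registry$records
  vals <- df[df$type_id == as.character(type_id),
             if (metric == "TRANSMISSION") "transmission" else "contrast"]
  if (length(vals) == 0L) {
    abort_endoqc(sprintf("no records for type '%s'", type_id),
                 "endoqc_no_baseline")
  }
  max(vals)
}

# Bests for both metrics at once; used by the decision engine.
bests_for_type <- function(registry, type_id) {
  c(TRANSMISSION = best_of_type(registry, type_id, "TRANSMISSION"),
    CONTRAST = best_of_type(registry, type_id, "CONTRAST"))
}

#' Export the registry to CSV
#'
#' Dialect: header `serial,type_id,timestamp,transmission,contrast,
#' moisture,context`, ISO-8601 UTC timestamps, UTF-8.
#'
#' @param registry an `endo_registry`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
registry_export <- function(registry, path) {
  df <- registry$records
  df <- df[order(df$serial, df$timestamp), , drop = FALSE]
  out <- data.frame(serial = df$serial, type_id = df$type_id,
                    timestamp = format_ts(df$timestamp),
                    transmission = df$transmission, contrast = df$contrast,
                    moisture = tolower(as.character(df$moisture)),
                    context = df$context, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Import a registry from CSV
#'
#' Inverse of [registry_export()]; every row is validated on insert.
#'
#' @param path CSV path in the export dialect.
#' @return an `endo_registry`.
#' @export
registry_import <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("serial", "type_id", "timestamp", "transmission", "contrast",
            "moisture", "context")
  if (!identical(names(df), need)) {
    abort_endoqc(sprintf("unexpected CSV header: %s",
                         paste(names(df), collapse = ",")),
                 "endoqc_io_error")
  }
  reg <- endo_registry()
  for (i in seq_len(nrow(df))) {
    add_record(reg, measurement_record(
      serial = df$serial[i], type_id = df$type_id[i],
      timestamp = parse_ts(df$timestamp[i]),
      transmission = df$transmission[i], contrast = df$contrast[i],
      moisture = identical(tolower(df$moisture[i]), "true"),
      context = df$context[i]))
  }
  reg
}
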