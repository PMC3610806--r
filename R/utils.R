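# Shared helpers: classed error conditions, scoped seeding, PGM image I/O.

#' Signal a classed endoqc error
#'
#' All package errors carry a class of the form `endoqc_<kind>` plus
#' `endoqc_error`, so callers can condition on the error kind rather than
#' matching message text.
#'
#' @param message error message.
#' @param class error kind, e.g. `"endoqc_invalid_argument"`.
#' @keywords internal
abort_endoqc <- function(message, class = "endoqc_invalid_argument") {
  stop(errorCondition(message, class = c(class, "endoqc_error")))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_endoqc(sprintf("`%s` must be a single non-missing number", name))
  }
  if (integer && x != as.integer(x)) {
    abort_endoqc(sprintf("`%s` must be an integer", name))
  }
  if (x < min || x > max) {
    abort_endoqc(sprintf("`%s` must be in [%s, %s], got %s",
                         name, min, max, x))
  }
  invisible(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation helpers do not
#' disturb the caller's RNG stream. With `seed = NULL` the code runs on the
#' ambient stream.
#'
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, kept inside 32-bit
# signed range (R integers).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index)) %% 2147483647)
}

#' Write an 8-bit greyscale image as ASCII PGM (P2)
#'
#' Plain-text portable greymap, readable by any image viewer and diff-able
#' in version control. Values are clamped to 0..255.
#'
#' @param pixels integer matrix of grey levels.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(pixels, path) {
  if (!is.matrix(pixels)) abort_endoqc("`pixels` must be a matrix")
  px <- pmin(pmax(round(pixels), 0L), 255L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(px, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path file written by [write_pgm()] or any P2 PGM.
#' @return integer matrix of grey levels.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(toks) < 4L || toks[1L] != "P2") {
    abort_endoqc(sprintf("'%s' is not an ASCII (P2) PGM file", path),
                 "endoqc_io_error")
  }
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) {
    abort_endoqc(sprintf("PGM '%s' has %d values, expected %d",
                         path, length(vals), w * h), "endoqc_io_error")
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# ISO-8601 UTC timestamp formatting used by every exporter.
format_ts <- function(ts) format(as.POSIXct(ts, tz = "UTC"),
                                 "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC")
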