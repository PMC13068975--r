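# Internal: evaluate `code` under a temporary RNG seed, restoring the caller's
# RNG state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' CGM sampling step in seconds (5 minutes)
#' @keywords internal
CGM_STEP_SECONDS <- 300L

#' Construct a glucose series on a regular 5-minute grid
#'
#' A `glucose_series` is one patient's CGM trace on a uniform time grid:
#' slot `i` (1-based) carries the timestamp `t0 + (i - 1) * 5 min`. Missing
#' slots are represented explicitly as `NA` in `values`; every present value
#' must be a finite glucose concentration > 0 mg/dL.
#'
#' Timestamps are timezone-naive local clock time (stored as POSIXct in UTC so
#' that arithmetic never crosses daylight-saving discontinuities): day-part and
#' hour-of-day features refer to the patient's local day.
#'
#' @param values numeric vector of glucose values in mg/dL; `NA` marks a
#'   missing grid slot.
#' @param t0 POSIXct (or coercible string) timestamp of the first grid slot.
#' @param patient_id opaque identifier string.
#' @return An object of class `glucose_series`.
#' @examples
#' gs <- glucose_series(c(100, 105, NA, 110), t0 = "2024-01-01 00:00:00")
#' n_slots(gs)
#' is_observed(gs)
#' @export
glucose_series <- function(values, t0, patient_id = "patient") {
  t0 <- as_grid_time(t0)
  values <- as.numeric(values)
  obs <- !is.na(values)
  if (any(!is.finite(values[obs]) | values[obs] <= 0)) {
    stop("all present glucose values must be finite and > 0 mg/dL")
  }
  structure(
    list(patient_id = as.character(patient_id), t0 = t0,
         step = CGM_STEP_SECONDS, values = values),
    class = "glucose_series"
  )
}

as_grid_time <- function(x) {
  if (is.character(x)) x <- as.POSIXct(x, tz = "UTC")
  if (!inherits(x, "POSIXct")) stop("timestamp must be POSIXct or a string")
  attr(x, "tzone") <- "UTC"
  x
}

#' @rdname glucose_series
#' @param x a `glucose_series`.
#' @export
n_slots <- function(x) length(x$values)

#' @rdname glucose_series
#' @export
is_observed <- function(x) !is.na(x$values)

#' @rdname glucose_series
#' @export
series_times <- function(x) x$t0 + (seq_along(x$values) - 1) * x$step

#' @export
print.glucose_series <- function(x, ...) {
  n <- n_slots(x)
  miss <- sum(is.na(x$values))
  cat(sprintf(
    "<glucose_series> patient=%s  n=%d slots (5-min grid)  missing=%d (%.1f%%)\n",
    x$patient_id, n, miss, if (n > 0) 100 * miss / n else 0))
  cat(sprintf("  start %s   end %s\n",
              format(x$t0, "%Y-%m-%d %H:%M"),
              format(x$t0 + (max(n, 1) - 1) * x$step, "%Y-%m-%d %H:%M")))
  invisible(x)
}

#' Read a raw CGM event list from CSV
#'
#' Parses a CSV file with a header naming a timestamp column (ISO 8601) and a
#' numeric glucose column. The result is a raw, time-ordered event list (class
#' `cgm_events`), not yet snapped to the 5-minute grid; pass it to
#' [regularize_to_grid()].
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector mapping the roles
#'   `timestamp` and `glucose` to column names in the file; defaults to
#'   columns literally named `timestamp` and `glucose`.
#' @param patient_id identifier attached to the series.
#' @return A `cgm_events` object: a data frame with columns `time` (POSIXct)
#'   and `glucose` (mg/dL), in file order.
#' @export
read_csv_series <- function(path, column_map = NULL, patient_id = NULL) {
  if (!file.exists(path)) stop("cannot read CGM file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ts_col <- if (!is.null(column_map) && "timestamp" %in% names(column_map)) {
    column_map[["timestamp"]]
  } else "timestamp"
  gl_col <- if (!is.null(column_map) && "glucose" %in% names(column_map)) {
    column_map[["glucose"]]
  } else "glucose"
  if (!all(c(ts_col, gl_col) %in% names(df))) {
    stop("CSV must have columns '", ts_col, "' and '", gl_col, "'")
  }
  if (nrow(df) == 0) stop("no records in ", path)
  tm <- parse_iso_times(df[[ts_col]])
  if (anyNA(tm)) {
    bad <- which(is.na(tm))[1]
    stop(sprintf("unparseable timestamp at row %d: '%s'", bad, df[[ts_col]][bad]))
  }
  gl <- df[[gl_col]]
  if (is.character(gl)) {
    glnum <- suppressWarnings(as.numeric(gl))
    if (anyNA(glnum) && !anyNA(gl)) {
      bad <- which(is.na(glnum))[1]
      stop(sprintf("non-numeric glucose at row %d: '%s'", bad, gl[bad]))
    }
    gl <- glnum
  }
  if (!is.numeric(gl)) stop("glucose column is not numeric")
  if (anyDuplicated(tm)) {
    dup <- tm[duplicated(tm)][1]
    stop("duplicate timestamp in ", path, ": ", format(dup, "%Y-%m-%d %H:%M:%S"))
  }
  cgm_events(tm, gl, patient_id = patient_id %||% tools::file_path_sans_ext(basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# element-wise ISO-8601-ish parsing: NA (not an error) for rows that match
# no accepted format, so callers can name the offending row
parse_iso_times <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%d %H:%M", "%Y/%m/%d %H:%M:%OS")
  res <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in formats) {
    idx <- which(is.na(res))
    if (length(idx) == 0) break
    p <- strptime(x[idx], fmt, tz = "UTC")
    ok <- !is.na(p)
    res[idx[ok]] <- as.POSIXct(p[ok], tz = "UTC")
  }
  res
}

#' @rdname read_csv_series
#' @param time POSIXct event times.
#' @param glucose numeric glucose values (mg/dL).
#' @export
cgm_events <- function(time, glucose, patient_id = "patient") {
  glucose <- as.numeric(glucose)
  if (any(!is.finite(glucose) | glucose <= 0)) {
    stop("all glucose event values must be finite and > 0 mg/dL")
  }
  structure(data.frame(time = as_grid_time(time), glucose = glucose),
            patient_id = as.character(patient_id),
            class = c("cgm_events", "data.frame"))
}

#' Read the CGM stream from an OhioT1DM-style XML document
#'
#' Extracts only the `glucose_level` event stream (children with `ts` and
#' `value` attributes, `ts` formatted day-month-year hour:minute:second); all
#' other event streams (meals, insulin, exercise, ...) are ignored.
#'
#' @param path path to the XML file.
#' @return A `cgm_events` object in document order.
#' @export
read_ohio_xml <- function(path) {
  if (!file.exists(path)) stop("cannot read XML file: ", path)
  doc <- xml2::read_xml(path)
  gl <- xml2::xml_find_first(doc, ".//glucose_level")
  if (inherits(gl, "xml_missing")) {
    stop("no <glucose_level> element found in ", path)
  }
  events <- xml2::xml_children(gl)
  if (length(events) == 0) stop("no records: <glucose_level> is empty in ", path)
  ts <- xml2::xml_attr(events, "ts")
  val <- xml2::xml_attr(events, "value")
  if (anyNA(ts) || anyNA(val)) {
    stop("glucose event missing 'ts' or 'value' attribute in ", path)
  }
  tm <- as.POSIXct(ts, format = "%d-%m-%Y %H:%M:%S", tz = "UTC")
  if (anyNA(tm)) {
    stop("unparseable glucose timestamp '", ts[which(is.na(tm))[1]], "' in ", path)
  }
  num <- suppressWarnings(as.numeric(val))
  if (anyNA(num)) {
    stop("non-numeric glucose value '", val[which(is.na(num))[1]], "' in ", path)
  }
  pid <- xml2::xml_attr(xml2::xml_root(doc), "id")
  cgm_events(tm, num, patient_id = if (is.na(pid)) "patient" else pid)
}

#' Snap raw CGM events onto the regular 5-minute grid
#'
#' Each event is snapped to the nearest grid slot (multiples of 5 minutes on
#' the absolute clock) provided it lies within `tolerance` seconds of that
#' slot; midpoint ties break toward the earlier slot. Unclaimed slots between
#' the first and last snapped event become missing (`NA`). If two events snap
#' to the same slot the nearer one is kept with a warning; events farther than
#' the tolerance from any slot are dropped with a warning and counted in the
#' `dropped` attribute of the result.
#'
#' Applying the function to an already-regular `glucose_series` is the
#' identity.
#'
#' @param raw a `cgm_events` event list or a `glucose_series`.
#' @param tolerance maximum snap distance in seconds (default 60).
#' @return A `glucose_series`; attribute `dropped` counts discarded events.
#' @export
regularize_to_grid <- function(raw, tolerance = 60) {
  if (inherits(raw, "glucose_series")) {
    obs <- is_observed(raw)
    if (!any(obs)) stop("no records: series is entirely missing")
    raw <- cgm_events(series_times(raw)[obs], raw$values[obs],
                      patient_id = raw$patient_id)
  }
  stopifnot(inherits(raw, "cgm_events"))
  pid <- attr(raw, "patient_id")
  ord <- order(raw$time)
  tm <- as.numeric(raw$time)[ord]
  gl <- raw$glucose[ord]

  step <- CGM_STEP_SECONDS
  # nearest multiple of step; exact midpoints (offset step/2) round down
  slot <- floor(tm / step + 0.5)
  at_mid <- (tm %% step) == step / 2
  slot[at_mid] <- slot[at_mid] - 1
  dist <- abs(tm - slot * step)

  keep <- dist <= tolerance
  dropped <- sum(!keep)
  if (dropped > 0) {
    warning(sprintf("%d event(s) farther than %gs from any 5-min slot dropped",
                    dropped, tolerance))
  }
  slot <- slot[keep]; gl <- gl[keep]; dist <- dist[keep]
  if (length(slot) == 0) stop("no records within tolerance of the grid")

  # collisions: keep the nearer event per slot (first on equal distance)
  if (anyDuplicated(slot)) {
    warning("multiple events snapped to the same grid slot; keeping the nearer")
    o <- order(slot, dist)
    slot <- slot[o]; gl <- gl[o]
    keep2 <- !duplicated(slot)
    slot <- slot[keep2]; gl <- gl[keep2]
  }

  first <- min(slot); last <- max(slot)
  values <- rep(NA_real_, last - first + 1)
  values[slot - first + 1] <- gl
  out <- glucose_series(values, t0 = as.POSIXct(first * step, origin = "1970-01-01", tz = "UTC"),
                        patient_id = pid)
  attr(out, "dropped") <- dropped
  out
}

#' Write / re-read a glucose series as CSV
#'
#' The canonical on-disk format: columns `timestamp, glucose`, one row per
#' observed slot; missing slots are simply absent and the mask is
#' reconstructed on read (via [regularize_to_grid()]). The round trip
#' `read_series_csv(write_series_csv(x))` reproduces values, mask and
#' timestamps exactly for any series whose first and last slots are observed.
#'
#' @param series a `glucose_series`.
#' @param path output CSV path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a `glucose_series`.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  obs <- is_observed(series)
  df <- data.frame(
    timestamp = format(series_times(series)[obs], "%Y-%m-%dT%H:%M:%S"),
    glucose = series$values[obs]
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @inheritParams read_csv_series
#' @export
read_series_csv <- function(path, patient_id = NULL) {
  regularize_to_grid(read_csv_series(path, patient_id = patient_id))
}
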