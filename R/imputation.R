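#' Locate maximal runs of missing slots
#'
#' @param series a `glucose_series` on the regular grid.
#' @return Data frame with one row per gap: `start` (1-based index of the
#'   first missing slot), `length`, and `boundary` (TRUE when the run touches
#'   the first or last slot of the series, where interpolation has no anchor
#'   on one side).
#' @export
find_gaps <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  miss <- is.na(series$values)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], length = r$lengths[keep])
  out$boundary <- out$start == 1L | (out$start + out$length - 1L) == length(miss)
  out
}

#' Route a gap to its imputation branch by length
#'
#' Thresholds: gaps of fewer than 12 consecutive missing slots are spline
#' interpolated; gaps of 12 to 50 slots are forecast with an ARIMA model;
#' gaps longer than 50 slots cut the series.
#'
#' @param length gap length(s), in slots (vectorized).
#' @return Character vector over `{"SPLINE", "ARIMA", "CUT"}`.
#' @export
route_gap <- function(length) {
  if (any(length < 1)) stop("gap length must be >= 1")
  ifelse(length <= 11, "SPLINE", ifelse(length <= 50, "ARIMA", "CUT"))
}

# Observed (non-NA) anchor indices within `width` slots on each side of a gap,
# capped at `max_each` per side.
gap_anchors <- function(values, gap, max_each = 50) {
  n <- length(values)
  left <- which(!is.na(values[seq_len(gap$start - 1)]))
  after <- gap$start + gap$length
  right <- if (after <= n) after - 1L + which(!is.na(values[after:n])) else integer(0)
  c(utils::tail(left, max_each), utils::head(right, max_each))
}

#' Fill a short gap by cubic spline interpolation
#'
#' Fits an interpolating cubic spline (Forsythe–Malcolm–Moler end conditions,
#' which reproduce cubic polynomials exactly) through the observed slots
#' flanking the gap and evaluates it at the missing slots. Observed slots are
#' never modified.
#'
#' @param series a `glucose_series`.
#' @param gap one-row gap descriptor (`start`, `length`) as from [find_gaps()].
#' @return The series with the gap's slots filled; attribute `provenance`
#'   marks the filled slot indices.
#' @export
fill_spline <- function(series, gap) {
  stopifnot(inherits(series, "glucose_series"))
  n <- n_slots(series)
  if (gap$start == 1 || gap$start + gap$length - 1 == n) {
    stop("boundary gap has no anchor on one side; escalate to CUT")
  }
  values <- series$values
  anchors <- gap_anchors(values, gap)
  if (length(anchors) < 4) {
    stop("fewer than 4 observed anchor points around gap; escalate to CUT")
  }
  idx <- gap$start:(gap$start + gap$length - 1)
  fitted <- stats::spline(anchors, values[anchors], xout = idx,
                          method = "fmm")$y
  values[idx] <- fitted
  out <- series
  out$values <- values
  attr(out, "provenance") <- idx
  out
}

ARIMA_MIN_HISTORY <- 50L
ARIMA_MAX_HISTORY <- 288L

# Fit an ARIMA model to `history` choosing (p, d, q) over p,q in 0..2 and
# d in 0..1 by AIC; returns NULL when nothing converges.
fit_arima_aic <- function(history) {
  best <- NULL; best_aic <- Inf
  for (d in 0:1) for (p in 0:2) for (q in 0:2) {
    fit <- tryCatch(
      suppressWarnings(stats::arima(history, order = c(p, d, q),
                                    method = "CSS-ML")),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$aic) && fit$aic < best_aic) {
      best <- fit; best_aic <- fit$aic
    }
  }
  best
}

#' Fill a medium gap by ARIMA forecasting
#'
#' An ARIMA model is fit to the contiguous run of non-missing slots
#' immediately preceding the gap (order selected by AIC over p, q in 0..2 and
#' d in 0..1; most recent 288 slots used at most) and the gap is filled with
#' the model's multi-step forecast. A history shorter than 50 slots falls
#' back to spline interpolation with a warning; if no candidate order
#' converges the fallback order (1,1,0) is tried, and failing that the gap is
#' escalated to CUT.
#'
#' @inheritParams fill_spline
#' @return The series with the gap filled; attribute `provenance` marks the
#'   filled indices, attribute `method` records `"arima"` or `"spline"`
#'   (fallback).
#' @export
fill_arima <- function(series, gap) {
  stopifnot(inherits(series, "glucose_series"))
  values <- series$values
  # contiguous observed run immediately before the gap
  run_len <- 0L
  i <- gap$start - 1L
  while (i >= 1 && !is.na(values[i])) { run_len <- run_len + 1L; i <- i - 1L }
  if (run_len < ARIMA_MIN_HISTORY) {
    warning(sprintf(
      "only %d contiguous slots precede gap at %d (< %d); falling back to spline",
      run_len, gap$start, ARIMA_MIN_HISTORY))
    out <- fill_spline(series, gap)
    attr(out, "method") <- "spline"
    return(out)
  }
  history <- values[(gap$start - min(run_len, ARIMA_MAX_HISTORY)):(gap$start - 1L)]
  idx <- gap$start:(gap$start + gap$length - 1)
  if (stats::sd(history) < 1e-8) {
    # degenerate (constant) history: the conditional expectation of any
    # ARIMA model fitted to a constant series is that constant
    values[idx] <- history[length(history)]
    out <- series
    out$values <- values
    attr(out, "provenance") <- idx
    attr(out, "method") <- "arima"
    return(out)
  }
  fit <- fit_arima_aic(history)
  if (is.null(fit)) {
    fit <- tryCatch(
      suppressWarnings(stats::arima(history, order = c(1, 1, 0),
                                    method = "CSS-ML")),
      error = function(e) NULL)
  }
  if (is.null(fit)) stop("ARIMA fit failed for gap; escalate to CUT")
  fc <- stats::predict(fit, n.ahead = gap$length)$pred
  values[idx] <- as.numeric(fc)
  out <- series
  out$values <- values
  attr(out, "provenance") <- idx
  attr(out, "method") <- "arima"
  out
}

#' Re-set implausible imputed values to missing
#'
#' Applied after ARIMA filling: an imputed slot is purged (set back to
#' missing) iff its value is outside the physiological range 40–400 mg/dL or
#' beyond mean ± 3 SD of the up to 24 originally observed values flanking the
#' gap (12 on each side, fewer near a series boundary). Only imputed slots
#' are ever examined; observed values — however extreme — are never flagged.
#'
#' @inheritParams fill_spline
#' @param filled the series returned by [fill_arima()] for `gap`.
#' @param observed_mask logical mask of originally observed slots.
#' @return The series with purged slots re-set to `NA`; attribute `purged`
#'   counts them.
#' @export
purge_imputed_outliers <- function(filled, gap, observed_mask) {
  values <- filled$values
  n <- length(values)
  idx <- gap$start:(gap$start + gap$length - 1)
  left_obs <- which(observed_mask[seq_len(gap$start - 1)])
  right_obs <- which(observed_mask)
  right_obs <- right_obs[right_obs > gap$start + gap$length - 1]
  flank <- c(utils::tail(left_obs, 12), utils::head(right_obs, 12))
  bad <- values[idx] < 40 | values[idx] > 400
  if (length(flank) >= 2) {
    m <- mean(values[flank]); s <- stats::sd(values[flank])
    bad <- bad | abs(values[idx] - m) > 3 * s
  }
  values[idx[bad]] <- NA_real_
  out <- filled
  out$values <- values
  attr(out, "purged") <- sum(bad)
  out
}

#' Hybrid gap imputation for training data
#'
#' Processes gaps left to right, routing each by length via [route_gap()]:
#' short gaps are spline interpolated; medium gaps are ARIMA-forecast, then
#' purged of implausible imputed values by [purge_imputed_outliers()] — if
#' fewer than 12 missing slots remain in the gap a second round of spline
#' interpolation fills them, otherwise the gap is escalated and the series is
#' partitioned there; long gaps (and gaps touching a series boundary, which
#' have no anchor on one side) cut the series. The result is a segmented
#' series: an ordered list of contiguous, fully valued segments.
#'
#' Observed values pass through bitwise unchanged, and every slot of the
#' input is accounted for: segment slots + cut-gap slots + escalated-gap
#' slots = n.
#'
#' @param series a regular-grid `glucose_series`.
#' @param min_usable_slots segments shorter than this (default 29: 11 warm-up
#'   rows + a 12-row window + a 6-step horizon) are kept but flagged
#'   unusable for window construction.
#' @return A `segmented_series`: list with `segments` (list of fully valued
#'   `glucose_series`), `provenance` (per-segment character vectors over
#'   `{"observed","spline","arima"}`), `usable` (logical per segment),
#'   `cuts` (data frame of dropped gap regions with a `reason`), and
#'   `log` (one row per gap: start, length, branch, purged, outcome).
#' @export
impute_hybrid <- function(series, min_usable_slots = 29L) {
  stopifnot(inherits(series, "glucose_series"))
  n <- n_slots(series)
  observed_mask <- is_observed(series)
  gaps <- find_gaps(series)

  values <- series$values
  provenance <- rep("observed", n)
  drop <- rep(FALSE, n)                       # slots removed by cutting
  cuts <- list(); logs <- list()

  work <- series
  for (k in seq_len(nrow(gaps))) {
    g <- gaps[k, ]
    idx <- g$start:(g$start + g$length - 1)
    branch <- if (g$boundary) "CUT" else route_gap(g$length)
    purged <- 0L; outcome <- branch

    if (branch == "SPLINE") {
      work$values <- values
      res <- tryCatch(fill_spline(work, g), error = function(e) e)
      if (inherits(res, "error")) {
        branch <- "CUT"; outcome <- "cut_no_anchors"
      } else {
        values <- res$values
        # imputed values are held to the CGM sensor range
        values[idx] <- pmin(pmax(values[idx], 40), 400)
        provenance[idx] <- "spline"
        outcome <- "spline"
      }
    } else if (branch == "ARIMA") {
      work$values <- values
      res <- tryCatch(fill_arima(work, g), error = function(e) e)
      if (inherits(res, "error")) {
        branch <- "CUT"; outcome <- "cut_arima_failed"
      } else {
        res <- purge_imputed_outliers(res, g, observed_mask)
        purged <- attr(res, "purged") %||% 0L
        remaining <- sum(is.na(res$values[idx]))
        if (remaining == 0) {
          values <- res$values
          provenance[idx] <- attr(res, "method") %||% "arima"
          outcome <- "arima"
        } else if (remaining < 12) {
          # second round of interpolation over the purged slots
          sub <- res
          sub_gaps <- find_gaps(sub)
          sub_gaps <- sub_gaps[sub_gaps$start %in% idx, , drop = FALSE]
          ok <- TRUE
          for (j in seq_len(nrow(sub_gaps))) {
            r2 <- tryCatch(fill_spline(sub, sub_gaps[j, ]), error = function(e) e)
            if (inherits(r2, "error")) { ok <- FALSE; break }
            sub$values <- r2$values
          }
          if (ok) {
            values <- sub$values
            values[idx] <- pmin(pmax(values[idx], 40), 400)
            provenance[idx] <- ifelse(is.na(res$values[idx]), "spline",
                                      attr(res, "method") %||% "arima")
            outcome <- "arima+respline"
          } else {
            branch <- "CUT"; outcome <- "cut_respline_failed"
          }
        } else {
          branch <- "CUT"; outcome <- "cut_purge_escalation"
        }
      }
    } else {
      outcome <- if (g$boundary) "cut_boundary" else "cut_long"
    }

    if (branch == "CUT") {
      drop[idx] <- TRUE
      cuts[[length(cuts) + 1]] <- data.frame(start = g$start, length = g$length,
                                             reason = outcome)
    }
    logs[[length(logs) + 1]] <- data.frame(
      start = g$start, length = g$length, branch = branch,
      purged = purged, outcome = outcome)
  }

  stopifnot(all(values[observed_mask] == series$values[observed_mask]))

  keep <- !drop
  r <- rle(keep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg_starts <- starts[r$values]; seg_ends <- ends[r$values]

  segments <- vector("list", length(seg_starts))
  prov_out <- vector("list", length(seg_starts))
  for (s in seq_along(seg_starts)) {
    rng <- seg_starts[s]:seg_ends[s]
    stopifnot(!anyNA(values[rng]))
    segments[[s]] <- glucose_series(
      values[rng], t0 = series$t0 + (seg_starts[s] - 1) * series$step,
      patient_id = series$patient_id)
    prov_out[[s]] <- provenance[rng]
  }
  usable <- vapply(segments, n_slots, 1L) >= min_usable_slots

  structure(list(
    segments = segments, provenance = prov_out, usable = usable,
    seg_starts = seg_starts,
    cuts = if (length(cuts)) do.call(rbind, cuts) else
      data.frame(start = integer(), length = integer(), reason = character()),
    log = if (length(logs)) do.call(rbind, logs) else
      data.frame(start = integer(), length = integer(), branch = character(),
                 purged = integer(), outcome = character()),
    n_input = n
  ), class = "segmented_series")
}

#' @export
print.segmented_series <- function(x, ...) {
  cat(sprintf("<segmented_series> %d segment(s) from %d input slots; %d usable\n",
              length(x$segments), x$n_input, sum(x$usable)))
  if (nrow(x$cuts)) {
    cat(sprintf("  %d cut region(s) dropping %d slots\n",
                nrow(x$cuts), sum(x$cuts$length)))
  }
  invisible(x)
}

#' Thresholdless imputation for inference data
#'
#' At inference time the series must stay in one piece: every interior gap is
#' spline interpolated regardless of length and the series is never cut;
#' imputed values are clipped to the 40-400 mg/dL sensor range (splines
#' extrapolate wildly across very long gaps). Leading/trailing missing runs
#' (which no interpolation can anchor) are trimmed. The returned mask marks the slots that were observed in the
#' original input, so that evaluation can be restricted to values that were
#' not null in the original file.
#'
#' @param series a regular-grid `glucose_series`.
#' @return List with `series` (fully valued, possibly boundary-trimmed),
#'   `observed` (logical mask, aligned with the returned series, of
#'   originally observed slots), and `offset` (slots trimmed from the start).
#' @export
impute_for_inference <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  obs <- is_observed(series)
  if (!any(obs)) stop("series is entirely missing")
  first <- which(obs)[1]; last <- max(which(obs))
  values <- series$values[first:last]
  trimmed <- glucose_series(values, t0 = series$t0 + (first - 1) * series$step,
                            patient_id = series$patient_id)
  mask <- !is.na(values)
  gaps <- find_gaps(trimmed)
  for (k in seq_len(nrow(gaps))) {
    trimmed <- fill_spline(trimmed, gaps[k, ])
    idx <- gaps$start[k]:(gaps$start[k] + gaps$length[k] - 1)
    # long uncut gaps can extrapolate wildly; imputed values are held to
    # the CGM sensor range (observed slots untouched)
    trimmed$values[idx] <- pmin(pmax(trimmed$values[idx], 40), 400)
  }
  stopifnot(!anyNA(trimmed$values))
  list(series = trimmed, observed = mask, offset = first - 1L)
}
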