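#' Canonical feature channel order
#'
#' The nine input channels fed to the forecaster, in their fixed order.
#' @export
FEATURE_CHANNELS <- c("glucose", "diff1", "diff6", "trend", "avg", "std",
                      "day_part", "day_of_week", "hour_of_day")

#' Calendar features from grid timestamps
#'
#' * `day_of_week`: Monday = 1 .. Sunday = 7.
#' * `hour_of_day`: clock hour 0..23 mapped to 1..24.
#' * `day_part`: the day split into 7 clock intervals —
#'   hours \[0,4) -> 1, \[4,8) -> 2, \[8,11) -> 3, \[11,14) -> 4,
#'   \[14,17) -> 5, \[17,21) -> 6, \[21,24) -> 7
#'   (night, early morning, morning, midday, afternoon, evening, late night).
#'
#' @param timestamps POSIXct vector (timezone-naive local clock time).
#' @return Data frame with integer columns `day_part`, `day_of_week`,
#'   `hour_of_day`.
#' @export
calendar_features <- function(timestamps) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  hour <- lt$hour
  dow <- ((lt$wday + 6L) %% 7L) + 1L          # POSIXlt: Sunday = 0
  day_part <- findInterval(hour, c(0, 4, 8, 11, 14, 17, 21))
  data.frame(day_part = as.integer(day_part),
             day_of_week = as.integer(dow),
             hour_of_day = as.integer(hour + 1L))
}

#' Glycemic state of a glucose value
#'
#' Classes: hypoglycemia below 70 mg/dL, normal 70–180 mg/dL (inclusive),
#' hyperglycemia above 180 mg/dL.
#'
#' @param glucose numeric glucose values, mg/dL (must be > 0).
#' @return Factor with levels `hypo`, `normal`, `hyper`.
#' @export
glycemic_label <- function(glucose) {
  if (any(!is.finite(glucose) | glucose <= 0)) {
    stop("glucose values must be finite and > 0 mg/dL")
  }
  factor(ifelse(glucose < 70, "hypo", ifelse(glucose <= 180, "normal", "hyper")),
         levels = c("hypo", "normal", "hyper"))
}

GLYCEMIC_CLASSES <- c("hypo", "normal", "hyper")

# rolling weighted sum of the trailing `length(w)` values (current included,
# weights applied oldest-first); NA-padded, and all-NA when the series is
# shorter than the window
roll_wsum <- function(x, w) {
  if (length(x) < length(w)) return(rep(NA_real_, length(x)))
  as.numeric(stats::filter(x, rev(w), sides = 1))
}

roll_sum <- function(x, width) roll_wsum(x, rep(1, width))

#' Derive the nine feature channels from a fully valued segment
#'
#' Per timestamp t (window = the trailing hour = 12 samples including t):
#' * `diff1`  = g(t) - g(t-1)
#' * `diff6`  = g(t) - g(t-6)
#' * `trend`  = least-squares slope of g over t-11..t, mg/dL per 5-min step
#' * `avg`    = mean of g over t-11..t
#' * `std`    = sample standard deviation of g over t-11..t
#' plus the [calendar_features()] and the glycemic label of g(t). Rows with
#' fewer than 12 samples of history (`t < 12`, 1-based) are marked invalid.
#'
#' @param segment a fully valued `glucose_series` (post-imputation).
#' @return A `feature_matrix`: data frame with `time`, the nine channels in
#'   [FEATURE_CHANNELS] order, `label`, and `valid`.
#' @export
derive_features <- function(segment) {
  stopifnot(inherits(segment, "glucose_series"))
  g <- segment$values
  if (anyNA(g)) stop("segment must be fully valued; impute first")
  L <- length(g)
  W <- 12L
  if (L < W) warning("segment shorter than 12 slots: all rows invalid")

  diff1 <- c(NA, diff(g))
  diff6 <- if (L > 6) c(rep(NA, 6), g[7:L] - g[seq_len(L - 6)]) else
    rep(NA_real_, L)

  # trailing-window mean / sd / OLS slope via rolling sums
  s1 <- roll_sum(g, W)
  s2 <- roll_sum(g^2, W)
  avg <- s1 / W
  std <- sqrt(pmax((s2 - s1^2 / W) / (W - 1), 0))
  # slope over x = 0..11: sum((x - xbar) g) / sum((x - xbar)^2); the weighted
  # rolling sum uses weights (x - 5.5) applied oldest-first
  xc <- (0:(W - 1)) - (W - 1) / 2
  denom <- sum(xc^2)                           # 143 for W = 12
  trend <- roll_wsum(g, xc) / denom

  cal <- calendar_features(series_times(segment))
  valid <- seq_len(L) >= W

  fm <- data.frame(
    time = series_times(segment),
    glucose = g, diff1 = diff1, diff6 = diff6, trend = trend,
    avg = avg, std = std,
    day_part = cal$day_part, day_of_week = cal$day_of_week,
    hour_of_day = cal$hour_of_day,
    label = glycemic_label(g),
    valid = valid
  )
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Fit the feature/target transformation on training rows
#'
#' Strictly positive, right-skewed channels are log transformed (`glucose`
#' and `avg`: natural log; `std`: log1p, since an in-range standard deviation
#' can be 0), signed channels (`diff1`, `diff6`, `trend`) stay linear; each of
#' these six is then standardized with training-set mean and SD. Calendar
#' channels are mapped onto \[0, 1\] by their fixed ranges. Parameters are
#' fitted once on training rows only and frozen; the glucose/target channel
#' transform is exactly invertible via [invert_target()].
#'
#' @param train_fm a `feature_matrix` (or rbind of several) of training rows;
#'   only rows with `valid == TRUE` contribute to the statistics.
#' @return A `transform_params` object.
#' @export
fit_transform <- function(train_fm) {
  stopifnot(inherits(train_fm, "data.frame"))
  rows <- train_fm[train_fm$valid, , drop = FALSE]
  if (nrow(rows) == 0) stop("no valid training rows to fit the transform on")
  kinds <- c(glucose = "log", diff1 = "identity", diff6 = "identity",
             trend = "identity", avg = "log", std = "log1p")
  center <- numeric(0); scale <- numeric(0)
  for (ch in names(kinds)) {
    v <- transform_raw(rows[[ch]], kinds[[ch]])
    center[ch] <- mean(v)
    s <- stats::sd(v)
    scale[ch] <- if (is.na(s) || s < 1e-12) 1 else s
  }
  structure(list(kinds = kinds, center = center, scale = scale,
                 calendar_div = c(day_part = 6, day_of_week = 6,
                                  hour_of_day = 23)),
            class = "transform_params")
}

transform_raw <- function(v, kind) {
  switch(kind, log = log(v), log1p = log1p(v), identity = v,
         stop("unknown transform kind: ", kind))
}

#' Apply a fitted transformation to a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param params a `transform_params` from [fit_transform()]; statistics are
#'   never recomputed here, so applying training parameters to test data
#'   cannot leak test information.
#' @return Numeric matrix, rows aligned with `fm`, columns exactly
#'   [FEATURE_CHANNELS].
#' @export
apply_transform <- function(fm, params) {
  if (!inherits(params, "transform_params")) {
    stop("transform parameters not fitted: call fit_transform() first")
  }
  out <- matrix(NA_real_, nrow(fm), length(FEATURE_CHANNELS),
                dimnames = list(NULL, FEATURE_CHANNELS))
  for (ch in names(params$kinds)) {
    out[, ch] <- (transform_raw(fm[[ch]], params$kinds[[ch]]) -
                    params$center[ch]) / params$scale[ch]
  }
  for (ch in names(params$calendar_div)) {
    out[, ch] <- (fm[[ch]] - 1) / params$calendar_div[ch]
  }
  out
}

#' Transform / invert a glucose target value
#'
#' `transform_target` maps mg/dL to the model's transformed target space;
#' `invert_target` is its exact inverse (round trip within 1e-9 over the
#' physiological range).
#'
#' @param glucose,z numeric vectors.
#' @param params a `transform_params`.
#' @export
transform_target <- function(glucose, params) {
  stopifnot(inherits(params, "transform_params"))
  (log(glucose) - params$center["glucose"]) / params$scale["glucose"]
}

#' @rdname transform_target
#' @export
invert_target <- function(z, params) {
  stopifnot(inherits(params, "transform_params"))
  unname(exp(z * params$scale["glucose"] + params$center["glucose"]))
}
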