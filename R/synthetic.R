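#' Configuration for the synthetic CGM simulator
#'
#' The simulator is a statistical fixture, not a metabolic model: it produces
#' traces with the gross features of real CGM data — a circadian baseline
#' oscillation, post-meal excursions with an hour-scale rise and a slower
#' decay, and autocorrelated sensor/physiology noise — clipped to the
#' physiological sensor range.
#'
#' @param days number of simulated days (288 slots each at 5-min sampling).
#' @param baseline mean glucose level, mg/dL.
#' @param circadian_amplitude amplitude of the 24-h sinusoid, mg/dL (trough in
#'   the early morning, peak in the late afternoon).
#' @param meal_times hours-of-day at which meals occur.
#' @param meal_amplitude_range interval (mg/dL) the lognormal peak meal
#'   excursion is clipped to.
#' @param meal_rise_minutes time from meal start to excursion peak.
#' @param meal_decay_minutes approximate total decay time of the excursion.
#' @param ar_coefficient lag-1 autocorrelation of the AR(1) noise, in [0, 1).
#' @param noise_sd marginal standard deviation of the noise, mg/dL.
#' @param floor,ceiling sensor clipping range, mg/dL.
#' @param seed RNG seed for the trace.
#' @return A `sim_config` list.
#' @export
sim_config <- function(days = 14, baseline = 120, circadian_amplitude = 15,
                       meal_times = c(8, 13, 19),
                       meal_amplitude_range = c(40, 90),
                       meal_rise_minutes = 30, meal_decay_minutes = 120,
                       ar_coefficient = 0.8, noise_sd = 5,
                       floor = 40, ceiling = 400, seed = 1L,
                       t0 = "2024-01-01 00:00:00", patient_id = "sim") {
  cfg <- list(days = as.integer(days), baseline = baseline,
              circadian_amplitude = circadian_amplitude,
              meal_times = meal_times,
              meal_amplitude_range = meal_amplitude_range,
              meal_rise_minutes = meal_rise_minutes,
              meal_decay_minutes = meal_decay_minutes,
              ar_coefficient = ar_coefficient, noise_sd = noise_sd,
              floor = floor, ceiling = ceiling, seed = as.integer(seed),
              t0 = t0, patient_id = patient_id)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$days < 1) stop("days must be >= 1")
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1) {
    stop("ar_coefficient must be in [0, 1)")
  }
  if (!(cfg$floor < cfg$baseline && cfg$baseline < cfg$ceiling)) {
    stop("must have floor < baseline < ceiling")
  }
  if (diff(cfg$meal_amplitude_range) < 0) stop("invalid meal_amplitude_range")
  invisible(cfg)
}

#' @rdname sim_config
#' @param t0,patient_id passed to the resulting [glucose_series()].
#' @export
simulate_trace <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$days * 288L
  minutes <- (seq_len(n) - 1) * 5            # minutes since t0
  hod <- (minutes / 60) %% 24

  circ <- config$circadian_amplitude * cos(2 * pi * (hod - 16) / 24)

  with_seed(config$seed, {
    meal <- numeric(n)
    if (length(config$meal_times) > 0 && diff(range(config$meal_amplitude_range)) >= 0) {
      # gamma-shaped excursion kernel: peak 1 at `rise` minutes after onset,
      # exponential tail with time constant decay/4
      theta <- max(config$meal_decay_minutes / 4, 1)
      shape <- 1 + config$meal_rise_minutes / theta
      mode_t <- (shape - 1) * theta
      kern <- function(tau) {
        out <- numeric(length(tau))
        pos <- tau > 0
        out[pos] <- (tau[pos] / mode_t)^(shape - 1) *
          exp(-(tau[pos] - mode_t) / theta)
        out
      }
      for (day in seq_len(config$days) - 1) {
        for (mt in config$meal_times) {
          onset <- day * 1440 + mt * 60 + stats::runif(1, -15, 15)
          amp <- stats::rlnorm(1, meanlog = log(mean(config$meal_amplitude_range)),
                               sdlog = 0.25)
          amp <- min(max(amp, config$meal_amplitude_range[1]),
                     config$meal_amplitude_range[2])
          tau <- minutes - onset
          idx <- which(tau > 0 & tau < config$meal_decay_minutes * 4)
          if (length(idx)) meal[idx] <- meal[idx] + amp * kern(tau[idx])
        }
      }
    }

    noise <- numeric(n)
    if (config$noise_sd > 0) {
      phi <- config$ar_coefficient
      innov_sd <- config$noise_sd * sqrt(1 - phi^2)
      eps <- stats::rnorm(n, 0, innov_sd)
      noise[1] <- stats::rnorm(1, 0, config$noise_sd)
      if (n > 1) for (i in 2:n) noise[i] <- phi * noise[i - 1] + eps[i]
    }

    values <- pmin(pmax(config$baseline + circ + meal + noise,
                        config$floor), config$ceiling)
    glucose_series(values, t0 = config$t0, patient_id = config$patient_id)
  })
}

#' Specification of missingness to inject into a simulated trace
#'
#' Gap lengths are drawn from a three-regime mixture mirroring the gap-length
#' routing thresholds of the imputation stage: short gaps of 1–11 slots,
#' medium gaps of 12–50 slots, long gaps of 51–150 slots, uniform within each
#' regime.
#'
#' @param rate_per_day expected number of gaps per simulated day.
#' @param length_mixture probabilities of the (short, medium, long) regimes;
#'   must sum to 1.
#' @param seed RNG seed for gap placement (independent of the trace seed).
#' @export
gap_spec <- function(rate_per_day = 3, length_mixture = c(0.6, 0.3, 0.1),
                     seed = 2L) {
  if (length(length_mixture) != 3 || any(length_mixture < 0) ||
      abs(sum(length_mixture) - 1) > 1e-9) {
    stop("length_mixture must be 3 non-negative probabilities summing to 1")
  }
  if (rate_per_day < 0) stop("rate_per_day must be >= 0")
  structure(list(rate_per_day = rate_per_day,
                 length_mixture = length_mixture, seed = as.integer(seed)),
            class = "gap_spec")
}

GAP_REGIME_BOUNDS <- list(short = c(1L, 11L), medium = c(12L, 50L),
                          long = c(51L, 150L))

#' Punch seeded gaps into a fully observed series
#'
#' Gaps are placed uniformly at random, non-overlapping and separated by at
#' least one observed slot, away from the first and last 12 slots of the
#' series. The observed values are never altered; the true gap locations are
#' returned so imputation accuracy can be scored against ground truth.
#'
#' @param series a fully observed `glucose_series`.
#' @param spec a [gap_spec()].
#' @return A list with elements `series` (the masked `glucose_series`) and
#'   `gaps` (data frame with columns `start`, `length`, 1-based slot indices).
#' @export
inject_missingness <- function(series, spec = gap_spec()) {
  stopifnot(inherits(series, "glucose_series"), inherits(spec, "gap_spec"))
  if (!all(is_observed(series))) stop("series must be fully observed")
  n <- n_slots(series)
  days <- n / 288
  with_seed(spec$seed, {
    n_gaps <- stats::rpois(1, spec$rate_per_day * days)
    starts <- integer(0); lengths <- integer(0)
    occupied <- rep(FALSE, n)   # gap slots plus 1-slot separation margins
    tries <- 0
    while (length(starts) < n_gaps && tries < 200 * max(n_gaps, 1)) {
      tries <- tries + 1
      regime <- GAP_REGIME_BOUNDS[[sample.int(3, 1, prob = spec$length_mixture)]]
      len <- sample.int(regime[2] - regime[1] + 1L, 1) + regime[1] - 1L
      lo <- 13L; hi <- n - 12L - len + 1L
      if (hi < lo) next
      st <- lo + sample.int(hi - lo + 1L, 1) - 1L
      span <- max(1, st - 1):min(n, st + len)
      if (any(occupied[span])) next
      if (sum(lengths) + len > 0.5 * n) {
        stop("requested gap mass exceeds 50% of the series")
      }
      occupied[span] <- TRUE
      starts <- c(starts, st); lengths <- c(lengths, len)
    }
    values <- series$values
    for (k in seq_along(starts)) {
      values[starts[k]:(starts[k] + lengths[k] - 1)] <- NA_real_
    }
    ord <- order(starts)
    out <- glucose_series(values, t0 = series$t0, patient_id = series$patient_id)
    list(series = out,
         gaps = data.frame(start = starts[ord], length = lengths[ord]))
  })
}
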