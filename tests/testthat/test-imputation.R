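test_that("gap finding matches a brute-force run-length scan", {
  # spec fixture: O,M,M,O,M,O
  s <- gs(c(100, NA, NA, 110, NA, 120))
  g <- find_gaps(s)
  expect_equal(g$start, c(2, 5))
  expect_equal(g$length, c(2, 1))
  expect_false(any(g$boundary))

  expect_equal(nrow(find_gaps(gs(c(100, 110, 120)))), 0)

  allmiss <- gs(rep(NA_real_, 5))
  ga <- find_gaps(allmiss)
  expect_equal(ga$length, 5)
  expect_true(ga$boundary)

  set.seed(42)
  for (rep in 1:20) {
    mask <- runif(60) < 0.3
    vals <- ifelse(mask, NA, 100 + rnorm(60))
    got <- find_gaps(gs(vals))
    want <- oracle_gaps(mask)
    expect_equal(got$start, want$start)
    expect_equal(got$length, want$length)
  }
})

test_that("gap routing follows the printed thresholds exhaustively", {
  lens <- 1:200
  branch <- route_gap(lens)
  expect_true(all(branch[lens <= 11] == "SPLINE"))
  expect_true(all(branch[lens >= 12 & lens <= 50] == "ARIMA"))
  expect_true(all(branch[lens >= 51] == "CUT"))
  expect_error(route_gap(0), ">= 1")
})

test_that("spline filling reproduces cubics and never touches observed slots", {
  poly <- function(t) 150 + 2 * t - 0.05 * t^2 + 5e-4 * t^3
  vals <- poly(0:39)
  vals[16:20] <- NA
  s <- gs(vals)
  filled <- fill_spline(s, find_gaps(s)[1, ])
  expect_lt(max(abs(filled$values[16:20] - poly(15:19))), 1e-6)
  obs <- !is.na(vals)
  expect_identical(filled$values[obs], vals[obs])

  # constant series stays constant
  cv <- rep(130, 20); cv[8:10] <- NA
  cs <- gs(cv)
  cf <- fill_spline(cs, find_gaps(cs)[1, ])
  expect_equal(cf$values[8:10], rep(130, 3))

  # boundary gap has no left anchor
  bv <- c(NA, NA, 120, 125, 130, 128)
  expect_error(fill_spline(gs(bv), find_gaps(gs(bv))[1, ]), "boundary gap")
})

test_that("ARIMA filling matches conditional expectations and fills exactly the gap", {
  # constant history: fill equals the constant
  cv <- c(rep(120, 100), rep(NA, 20), rep(120, 30))
  cs <- gs(cv)
  cf <- fill_arima(cs, find_gaps(cs)[1, ])
  expect_lt(max(abs(cf$values[101:120] - 120)), 1e-3)
  expect_identical(is.na(cf$values), rep(FALSE, 150))
  expect_identical(cf$values[1:100], cv[1:100])

  # AR(1) history: forecasts decay geometrically toward the mean,
  # matching the closed-form conditional expectation
  set.seed(10)
  phi <- 0.8; m <- 120; n <- 2000
  innov <- 5 * sqrt(1 - phi^2)
  x <- as.numeric(m + arima.sim(list(ar = phi), n, sd = innov))
  tail_part <- as.numeric(m + arima.sim(list(ar = phi), 60, sd = innov))
  vals <- c(x, rep(NA, 20), tail_part)
  s <- gs(vals)
  f <- fill_arima(s, find_gaps(s)[1, ])
  closed_form <- m + phi^(1:20) * (x[n] - m)
  expect_lt(max(abs(f$values[(n + 1):(n + 20)] - closed_form)), 2)

  # short preceding history falls back to spline with a warning
  sv <- c(100 + sin(1:30 / 3) * 10, rep(NA, 15), 100 + sin(46:80 / 3) * 10)
  ss <- gs(sv)
  expect_warning(sf <- fill_arima(ss, find_gaps(ss)[1, ]), "falling back to spline")
  expect_equal(attr(sf, "method"), "spline")
  expect_false(anyNA(sf$values))
})

test_that("outlier purge flags only implausible imputed slots", {
  base <- c(rep(120, 30), rep(NA, 15), rep(122, 30))
  s <- gs(base)
  gap <- find_gaps(s)[1, ]
  obs_mask <- !is.na(base)

  # in-range fill close to the flanks: nothing purged
  ok <- s; ok$values[31:45] <- seq(120, 122, length.out = 15)
  pu <- purge_imputed_outliers(ok, gap, obs_mask)
  expect_equal(attr(pu, "purged"), 0)
  expect_false(anyNA(pu$values))

  # one fill of 700 violates the physiological cap
  wild <- ok; wild$values[38] <- 700
  pw <- purge_imputed_outliers(wild, gap, obs_mask)
  expect_equal(attr(pw, "purged"), 1)
  expect_true(is.na(pw$values[38]))

  # values outside flank mean +/- 3 SD are purged even when in 40..400
  flanky <- gs(c(100 + rnorm(30, sd = 2), rep(NA, 15), 100 + rnorm(30, sd = 2)))
  ff <- flanky; ff$values[31:45] <- 100; ff$values[40] <- 250
  pf <- purge_imputed_outliers(ff, gap, obs_mask)
  expect_true(is.na(pf$values[40]))

  # an extreme *observed* value elsewhere is never examined
  withobs <- ok; withobs$values[10] <- 350
  po <- purge_imputed_outliers(withobs, gap, !is.na(base))
  expect_equal(po$values[10], 350)
})

test_that("hybrid imputation routes, fills, and cuts per the flowchart", {
  set.seed(21)
  smooth <- 120 + 30 * sin((1:500) / 25) + rnorm(500, sd = 1)
  vals <- smooth
  vals[101:105] <- NA                       # 5 -> spline
  vals[201:220] <- NA                       # 20 -> arima
  vals[301:360] <- NA                       # 60 -> cut
  seg <- impute_hybrid(gs(vals))

  expect_equal(seg$log$branch, c("SPLINE", "ARIMA", "CUT"))
  expect_equal(length(seg$segments), 2)
  expect_true(all(vapply(seg$segments, function(s) !anyNA(s$values), TRUE)))
  expect_equal(seg$cuts$length, 60)

  # provenance marks imputed slots within the first segment
  expect_equal(sum(seg$provenance[[1]] == "spline"), 5)
  expect_equal(sum(seg$provenance[[1]] == "arima"), 20)

  # gapless series: single segment identical to the input
  clean <- impute_hybrid(gs(smooth))
  expect_equal(length(clean$segments), 1)
  expect_identical(clean$segments[[1]]$values, smooth)
  expect_true(all(clean$provenance[[1]] == "observed"))
})

test_that("a heavily purged medium gap escalates to a cut", {
  base <- c(rep(120, 60), rep(NA, 20), rep(121, 60))
  s <- gs(base)
  # force the ARIMA branch to return an implausible fill for 15 of 20 slots
  local_mocked_bindings(
    fill_arima = function(series, gap) {
      out <- series
      idx <- gap$start:(gap$start + gap$length - 1)
      out$values[idx] <- c(rep(120.5, 5), rep(700, 15))
      attr(out, "provenance") <- idx
      attr(out, "method") <- "arima"
      out
    },
    .package = "cgmforecast"
  )
  seg <- impute_hybrid(s)
  expect_equal(seg$log$outcome, "cut_purge_escalation")
  expect_equal(length(seg$segments), 2)
  # conservation: segments + dropped gap account for every input slot
  expect_equal(sum(vapply(seg$segments, n_slots, 1L)) + sum(seg$cuts$length), 140)
})

test_that("boundary gaps are always cut and short remnants flagged unusable", {
  vals <- c(rep(NA, 5), 120 + sin(1:40), rep(NA, 4))
  seg <- impute_hybrid(gs(vals))
  expect_true(all(grepl("cut_boundary", seg$log$outcome)))
  expect_equal(length(seg$segments), 1)
  expect_equal(n_slots(seg$segments[[1]]), 40)

  tiny <- impute_hybrid(gs(120 + sin(1:20)))
  expect_false(any(tiny$usable))
  long <- impute_hybrid(gs(120 + sin(1:29)))
  expect_true(all(long$usable))
})

test_that("observed slots survive hybrid imputation bitwise across random masks", {
  tr <- sim_small(days = 3, seed = 15)
  n <- n_slots(tr)
  for (seed in 1:12) {
    inj <- inject_missingness(tr, gap_spec(rate_per_day = 4, seed = seed))
    seg <- impute_hybrid(inj$series)
    # reconstruct the kept slots and compare to the original observed values
    total <- sum(vapply(seg$segments, n_slots, 1L)) + sum(seg$cuts$length)
    expect_equal(total, n)
    for (k in seq_along(seg$segments)) {
      rng <- seg$seg_starts[k]:(seg$seg_starts[k] + n_slots(seg$segments[[k]]) - 1)
      obs_here <- !is.na(inj$series$values[rng])
      expect_identical(seg$segments[[k]]$values[obs_here],
                       inj$series$values[rng][obs_here])
      expect_false(anyNA(seg$segments[[k]]$values))
    }
  }
})

test_that("imputation accuracy ordering: spline short < arima medium < persistence medium", {
  tr <- simulate_trace(sim_config(days = 10, seed = 31))
  truth <- tr$values
  n <- n_slots(tr)

  punch <- function(starts, len) {
    v <- truth
    for (s in starts) v[s:(s + len - 1)] <- NA
    gs(v)
  }
  short_starts <- seq(100, n - 200, by = 400)
  med_starts <- seq(150, n - 200, by = 400)

  s_short <- punch(short_starts, 8)
  gsh <- find_gaps(s_short)
  for (k in seq_len(nrow(gsh))) s_short <- fill_spline(s_short, gsh[k, ])
  idx_s <- unlist(lapply(short_starts, function(s) s:(s + 7)))
  rmse_spline <- sqrt(mean((s_short$values[idx_s] - truth[idx_s])^2))

  s_med <- punch(med_starts, 30)
  gm <- find_gaps(s_med)
  filled_med <- s_med
  for (k in seq_len(nrow(gm))) filled_med <- fill_arima(filled_med, gm[k, ])
  idx_m <- unlist(lapply(med_starts, function(s) s:(s + 29)))
  rmse_arima <- sqrt(mean((filled_med$values[idx_m] - truth[idx_m])^2))

  # persistence extension: carry the last pre-gap value across the gap
  pers <- s_med$values
  for (s in med_starts) pers[s:(s + 29)] <- pers[s - 1]
  rmse_pers <- sqrt(mean((pers[idx_m] - truth[idx_m])^2))

  expect_lt(rmse_spline, rmse_arima)
  expect_lt(rmse_arima, rmse_pers)
})

test_that("inference-time imputation fills everything and never cuts", {
  set.seed(4)
  vals <- 120 + 25 * sin((1:400) / 20) + rnorm(400, sd = 1)
  vals[100:179] <- NA                       # an 80-slot gap: cut in training,
  res <- impute_for_inference(gs(vals))     # spline-filled at inference
  expect_equal(n_slots(res$series), 400)
  expect_false(anyNA(res$series$values))
  expect_identical(res$observed, !is.na(vals))

  # observed values untouched; mask marks exactly the original observations
  obs <- !is.na(vals)
  expect_identical(res$series$values[obs], vals[obs])

  # gapless series: identity with an all-true mask
  clean <- impute_for_inference(gs(vals[!is.na(vals)]))
  expect_true(all(clean$observed))

  # leading missing slots are trimmed and reported via the offset
  lead <- c(rep(NA, 3), vals[!is.na(vals)][1:50])
  lr <- impute_for_inference(gs(lead))
  expect_equal(lr$offset, 3)
  expect_equal(n_slots(lr$series), 50)
})
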