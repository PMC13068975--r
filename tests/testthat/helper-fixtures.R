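# Shared fixtures and independent oracles used across the suite.

T0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")  # a Monday

# build a glucose_series directly from values (NA = missing)
gs <- function(values, t0 = T0) glucose_series(values, t0 = t0)

# write a small CSV trace and return its path
write_trace_csv <- function(times, glucose, path = tempfile(fileext = ".csv")) {
  df <- data.frame(timestamp = format(times, "%Y-%m-%dT%H:%M:%S"),
                   glucose = glucose)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# brute-force run-length scan for missing runs (independent of find_gaps)
oracle_gaps <- function(mask_missing) {
  out <- data.frame(start = integer(), length = integer())
  i <- 1; n <- length(mask_missing)
  while (i <= n) {
    if (mask_missing[i]) {
      j <- i
      while (j < n && mask_missing[j + 1]) j <- j + 1
      out <- rbind(out, data.frame(start = i, length = j - i + 1))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# naive per-row recomputation of the derived feature channels
oracle_features <- function(g) {
  L <- length(g)
  out <- data.frame(diff1 = rep(NA_real_, L), diff6 = NA_real_,
                    trend = NA_real_, avg = NA_real_, std = NA_real_)
  for (t in seq_len(L)) {
    if (t >= 2) out$diff1[t] <- g[t] - g[t - 1]
    if (t >= 7) out$diff6[t] <- g[t] - g[t - 6]
    if (t >= 12) {
      w <- g[(t - 11):t]
      x <- 0:11
      out$trend[t] <- stats::coef(stats::lm(w ~ x))[2]
      out$avg[t] <- mean(w)
      out$std[t] <- stats::sd(w)
    }
  }
  out
}

# independent Clarke Error Grid reference: scalar translation of the classic
# published inequalities, if/else chain per point
oracle_ceg <- function(ref, pred) {
  vapply(seq_along(ref), function(i) {
    r <- ref[i]; p <- pred[i]
    if ((r <= 70 && p <= 70) || (p <= 1.2 * r && p >= 0.8 * r)) {
      "A"
    } else if ((r >= 180 && p <= 70) || (r <= 70 && p >= 180)) {
      "E"
    } else if ((r >= 70 && r <= 290 && p >= r + 110) ||
               (r >= 130 && r <= 180 && p <= (7 / 5) * r - 182)) {
      "C"
    } else if ((r >= 240 && p >= 70 && p <= 180) ||
               (r <= 175 / 3 && p <= 180 && p >= 70) ||
               (r >= 175 / 3 && r <= 70 && p >= (6 / 5) * r)) {
      "D"
    } else "B"
  }, character(1))
}

# independent multiclass MCC via the Pearson correlation of one-hot codings:
# cov(X, Y) / sqrt(cov(X, X) cov(Y, Y)) with covariances summed over classes
oracle_mcc <- function(cm) {
  k <- nrow(cm)
  counts <- as.vector(t(cm))                  # row-major: (true i, pred j)
  truth <- rep(rep(seq_len(k), each = k), times = counts)
  pred <- rep(rep(seq_len(k), times = k), times = counts)
  n <- length(truth)
  X <- outer(truth, seq_len(k), "==") * 1
  Y <- outer(pred, seq_len(k), "==") * 1
  covs <- function(A, B) sum(vapply(seq_len(k), function(j) {
    sum((A[, j] - mean(A[, j])) * (B[, j] - mean(B[, j]))) / n
  }, 1.0))
  den <- sqrt(covs(X, X) * covs(Y, Y))
  if (den == 0) return(0)
  covs(X, Y) / den
}

# small fully-observed synthetic trace shared by several tests
sim_small <- function(days = 2, seed = 7) simulate_trace(sim_config(days = days, seed = seed))
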