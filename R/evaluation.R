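#' Regression metrics for glucose forecasts
#'
#' @param y_true,y_pred equal-length numeric vectors, mg/dL.
#' @return List with `rmse`, `mae` (mg/dL) and `r2` (1 - SSE/SST about the
#'   true mean; `NA` with a warning when `y_true` is constant).
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty input")
  err <- y_pred - y_true
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  sst <- sum((y_true - mean(y_true))^2)
  r2 <- if (sst == 0) {
    warning("r2 undefined: y_true is constant")
    NA_real_
  } else 1 - sum(err^2) / sst
  list(rmse = rmse, mae = mae, r2 = r2)
}

#' 3x3 confusion matrix over glycemic classes
#'
#' Rows are the true class, columns the predicted class, in the order
#' hypo, normal, hyper.
#'
#' @param true_labels,pred_labels factors from [glycemic_label()] (or vectors
#'   coercible to them).
#' @export
confusion_matrix3 <- function(true_labels, pred_labels) {
  t_f <- factor(true_labels, levels = GLYCEMIC_CLASSES)
  p_f <- factor(pred_labels, levels = GLYCEMIC_CLASSES)
  if (length(t_f) != length(p_f)) stop("length mismatch")
  unclass(table(true = t_f, predicted = p_f))
}

#' Multiclass Matthews correlation coefficient
#'
#' Generalized (here 3-class) MCC from a confusion matrix:
#' \deqn{(c s - \sum_k p_k t_k) / \sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}
#' where c is the trace, s the total count, and t_k, p_k the row (true) and
#' column (predicted) sums. A degenerate denominator (all truth or all
#' predictions in one class) yields 0 with a warning.
#'
#' @param cm square numeric matrix of non-negative counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc_multiclass <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative")
  s <- sum(cm)
  if (s <= 0) stop("empty confusion matrix")
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) {
    warning("MCC denominator degenerate; returning 0")
    return(0)
  }
  num / den
}

#' Per-class precision, recall and F1
#'
#' Zero denominators (a class never predicted or never present) yield 0 with
#' a warning.
#'
#' @param cm 3x3 confusion matrix (rows true, columns predicted).
#' @return Data frame with one row per class.
#' @export
class_metrics <- function(cm) {
  cm <- as.matrix(cm)
  k <- nrow(cm)
  res <- data.frame(class = rownames(cm) %||% GLYCEMIC_CLASSES[seq_len(k)],
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  for (i in seq_len(k)) {
    tp <- cm[i, i]; fp <- sum(cm[, i]) - tp; fn <- sum(cm[i, ]) - tp
    prec <- if (tp + fp == 0) { warning("class never predicted: precision 0"); 0 }
      else tp / (tp + fp)
    rec <- if (tp + fn == 0) { warning("class never present: recall 0"); 0 }
      else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    res[i, 2:4] <- c(prec, rec, f1)
  }
  res
}

#' Clarke Error Grid zone of a (reference, predicted) glucose pair
#'
#' Classifies each pair into the clinical accuracy zones A–E of the Clarke
#' Error Grid using the standard piecewise-linear inequalities, evaluated in
#' the fixed order A, E, C, D, else B (first match wins):
#' * A: both <= 70, or relative error <= 20%
#' * E: (ref >= 180 and pred <= 70) or (ref <= 70 and pred >= 180)
#' * C: (70 <= ref <= 290 and pred >= ref + 110) or
#'      (130 <= ref <= 180 and pred <= 7/5 ref - 182)
#' * D: (ref >= 240 and 70 <= pred <= 180) or (ref <= 175/3 and
#'      70 <= pred <= 180) or (175/3 <= ref <= 70 and pred >= 6/5 ref)
#' * B: everything else
#'
#' @param reference,predicted numeric vectors, mg/dL, in (0, 600].
#' @return Character vector of zones.
#' @export
ceg_zone <- function(reference, predicted) {
  if (length(reference) != length(predicted)) stop("length mismatch")
  if (any(reference <= 0 | reference > 600 | predicted <= 0 | predicted > 600)) {
    stop("glucose values must lie in (0, 600] mg/dL")
  }
  ref <- reference; pred <- predicted
  zone <- rep(NA_character_, length(ref))

  a <- (ref <= 70 & pred <= 70) | (abs(pred - ref) <= 0.2 * ref)
  e <- (ref >= 180 & pred <= 70) | (ref <= 70 & pred >= 180)
  cc <- (ref >= 70 & ref <= 290 & pred >= ref + 110) |
    (ref >= 130 & ref <= 180 & pred <= (7 / 5) * ref - 182)
  d <- (ref >= 240 & pred >= 70 & pred <= 180) |
    (ref <= 175 / 3 & pred >= 70 & pred <= 180) |
    (ref >= 175 / 3 & ref <= 70 & pred >= (6 / 5) * ref)

  zone[is.na(zone) & a] <- "A"
  zone[is.na(zone) & e] <- "E"
  zone[is.na(zone) & cc] <- "C"
  zone[is.na(zone) & d] <- "D"
  zone[is.na(zone)] <- "B"
  zone
}

#' Full clinical evaluation of a forecast run
#'
#' Computes regression metrics, the 3-class glycemic confusion analysis
#' (labels derived from both truth and forecast via [glycemic_label()]), and
#' Clarke Error Grid zone percentages — all restricted to target slots that
#' were observed in the original input (`mask`), i.e. never scored against
#' values that were themselves imputed.
#'
#' @param y_true,y_pred aligned sequences in mg/dL.
#' @param mask logical vector: TRUE where the target slot was originally
#'   observed. Defaults to all-TRUE.
#' @return An `eval_report`: list with `n`, `rmse`, `mae`, `r2`, `mcc`,
#'   `confusion`, `class_metrics`, and `ceg_percent` (named A–E, summing
#'   to 100).
#' @export
evaluate_forecasts <- function(y_true, y_pred, mask = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(mask)) mask <- rep(TRUE, length(y_true))
  if (length(mask) != length(y_true)) stop("mask length mismatch")
  yt <- y_true[mask]; yp <- y_pred[mask]
  if (length(yt) == 0) stop("no originally observed target slots to evaluate")

  reg <- regression_metrics(yt, yp)
  cm <- confusion_matrix3(glycemic_label(yt), glycemic_label(yp))
  mcc <- suppressWarnings(mcc_multiclass(cm))
  cls <- suppressWarnings(class_metrics(cm))

  zones <- ceg_zone(pmin(yt, 600), pmin(yp, 600))
  ceg <- 100 * vapply(c("A", "B", "C", "D", "E"),
                      function(z) mean(zones == z), 1.0)

  structure(list(n = length(yt), rmse = reg$rmse, mae = reg$mae, r2 = reg$r2,
                 mcc = mcc, confusion = cm, class_metrics = cls,
                 ceg_percent = ceg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_report> n=%d\n", x$n))
  cat(sprintf("  RMSE %.2f mg/dL   MAE %.2f mg/dL   R2 %.3f   MCC %.3f\n",
              x$rmse, x$mae, x$r2, x$mcc))
  cat("  CEG zones (%):",
      paste(sprintf("%s %.2f", names(x$ceg_percent), x$ceg_percent),
            collapse = "  "), "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  out <- list(n = report$n, rmse = report$rmse, mae = report$mae,
              r2 = report$r2, mcc = report$mcc,
              ceg_percent = as.list(report$ceg_percent),
              class_metrics = report$class_metrics,
              confusion = as.data.frame(as.table(report$confusion)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
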