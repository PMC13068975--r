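#' Full run configuration
#'
#' One configuration object fully determines a training or inference run:
#' the simulator settings (when the input is synthetic), the model
#' hyperparameters, and a single global seed from which every per-stage seed
#' is derived (trace seed, gap seed, model seed), so stages can be re-run in
#' isolation and identical configs give identical artifacts.
#'
#' @param sim a [sim_config()] (used by [simulate_trace()] when no file input
#'   is given).
#' @param model a [model_config()].
#' @param seed global seed; per-stage seeds are derived as small fixed
#'   offsets of it.
#' @param log_level one of "quiet", "info".
#' @export
run_config <- function(sim = NULL, model = NULL, seed = 1L,
                       log_level = "info") {
  seed <- as.integer(seed)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  sim$seed <- sim$seed %||% seed
  if (is.null(model)) model <- model_config(seed = seed + 2L)
  structure(list(sim = sim, model = model, seed = seed,
                 gap_seed = seed + 1L, log_level = log_level),
            class = "run_config")
}

pipe_log <- function(config, stage, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

abort_stage <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the training pipeline on one CGM trace
#'
#' Stages, in order: grid regularization, hybrid gap imputation
#' ([impute_hybrid()]), feature derivation per usable segment, transform
#' fitting on the training rows, window construction, and model training.
#' Each stage logs its counts (gaps per branch, segments, windows). One
#' model is fit per input trace (per patient).
#'
#' @param series a `glucose_series` or `cgm_events`, or a path to a CSV
#'   trace.
#' @param config a [run_config()].
#' @return `train_artifacts`: list with `model`, `transform`
#'   (`transform_params`), `model_config`, `segmented` (the
#'   `segmented_series`), `train_result`, and `counts` (named stage
#'   statistics).
#' @export
run_train_pipeline <- function(series, config = run_config()) {
  series <- tryCatch(ingest_series(series),
                     error = function(e) abort_stage("ingest", e))

  seg <- tryCatch(impute_hybrid(series),
                  error = function(e) abort_stage("impute", e))
  branch_counts <- table(factor(seg$log$branch,
                                levels = c("SPLINE", "ARIMA", "CUT")))
  pipe_log(config, "impute",
           "%d gap(s): %d spline, %d arima, %d cut -> %d segment(s) (%d usable)",
           nrow(seg$log), branch_counts["SPLINE"], branch_counts["ARIMA"],
           branch_counts["CUT"], length(seg$segments), sum(seg$usable))

  feats <- tryCatch(
    lapply(seg$segments[seg$usable], derive_features),
    error = function(e) abort_stage("features", e))
  if (length(feats) == 0) abort_stage("features",
                                      simpleError("no usable segments"))
  tparams <- tryCatch(fit_transform(do.call(rbind, feats)),
                      error = function(e) abort_stage("transform", e))
  pipe_log(config, "features", "%d segment(s), %d valid rows",
           length(feats), sum(vapply(feats, function(f) sum(f$valid), 1L)))

  windows <- tryCatch(make_windows(feats, tparams, config$model),
                      error = function(e) abort_stage("windows", e))
  pipe_log(config, "windows", "%d supervised window(s)", n_windows(windows))

  fit <- tryCatch(train_model(windows, config$model),
                  error = function(e) abort_stage("train", e))
  pipe_log(config, "train", "best epoch %d, validation RMSE %.4f (transformed)",
           fit$best_epoch, fit$best_val_rmse)

  structure(list(
    model = fit$model, transform = tparams, model_config = config$model,
    segmented = seg, train_result = fit,
    counts = list(gaps = nrow(seg$log),
                  gaps_spline = unname(branch_counts["SPLINE"]),
                  gaps_arima = unname(branch_counts["ARIMA"]),
                  gaps_cut = unname(branch_counts["CUT"]),
                  segments = length(seg$segments),
                  usable_segments = sum(seg$usable),
                  windows = n_windows(windows))
  ), class = "train_artifacts")
}

ingest_series <- function(series) {
  if (is.character(series)) series <- read_csv_series(series)
  if (inherits(series, "cgm_events")) series <- regularize_to_grid(series)
  if (!inherits(series, "glucose_series")) {
    stop("input must be a glucose_series, cgm_events, or CSV path")
  }
  series
}

#' Run the inference/evaluation pipeline on a test trace
#'
#' The deliberately different test-time preprocessing: every gap is spline
#' interpolated without thresholds and the series is never cut
#' ([impute_for_inference()]); features are derived and the training-time
#' transform is applied frozen (never refit); windows are built over the
#' single uncut series; forecasts (model and persistence baseline) are then
#' scored only at target slots that were observed in the original file.
#'
#' @param series test trace (same accepted forms as [run_train_pipeline()]).
#' @param artifacts `train_artifacts` from [run_train_pipeline()].
#' @param config a [run_config()] (logging only).
#' @return List with `report` (model `eval_report`),
#'   `persistence_report`, `forecasts`, `persistence`, `windows`, and
#'   `observed_mask` (per-window: was the target slot originally observed).
#' @export
run_eval_pipeline <- function(series, artifacts, config = run_config()) {
  stopifnot(inherits(artifacts, "train_artifacts"))
  series <- tryCatch(ingest_series(series),
                     error = function(e) abort_stage("ingest", e))

  imp <- tryCatch(impute_for_inference(series),
                  error = function(e) abort_stage("impute", e))
  pipe_log(config, "impute", "%d slot(s), %d originally observed, no cuts",
           n_slots(imp$series), sum(imp$observed))

  fm <- tryCatch(derive_features(imp$series),
                 error = function(e) abort_stage("features", e))
  windows <- tryCatch(
    make_windows(list(fm), artifacts$transform, artifacts$model_config),
    error = function(e) abort_stage("windows", e))
  if (n_windows(windows) == 0) abort_stage("windows",
                                           simpleError("test trace too short"))

  fc <- tryCatch(predict_glucose(artifacts$model, windows, artifacts$transform),
                 error = function(e) abort_stage("predict", e))
  base <- persistence_baseline(windows)

  target_observed <- imp$observed[windows$target_index]
  report <- tryCatch(
    evaluate_forecasts(windows$targets_mgdl, fc, target_observed),
    error = function(e) abort_stage("evaluate", e))
  persistence_report <- evaluate_forecasts(windows$targets_mgdl, base,
                                           target_observed)
  pipe_log(config, "evaluate",
           "n=%d  model RMSE %.2f mg/dL  persistence RMSE %.2f mg/dL",
           report$n, report$rmse, persistence_report$rmse)

  list(report = report, persistence_report = persistence_report,
       forecasts = fc, persistence = base, windows = windows,
       observed_mask = target_observed)
}

#' Persist / restore training artifacts
#'
#' Weights, transform parameters and the model configuration are written
#' together so that prediction from a saved run is self-contained.
#'
#' @param artifacts `train_artifacts`.
#' @param dir output directory (created if needed).
#' @export
save_artifacts <- function(artifacts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(artifacts[c("model", "transform", "model_config")],
          file.path(dir, "artifacts.rds"))
  jsonlite::write_json(artifacts$counts, file.path(dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_artifacts
#' @export
load_artifacts <- function(dir) {
  a <- readRDS(file.path(dir, "artifacts.rds"))
  structure(list(model = a$model, transform = a$transform,
                 model_config = a$model_config),
            class = "train_artifacts")
}
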