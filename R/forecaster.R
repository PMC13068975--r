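#' Forecaster hyperparameter configuration
#'
#' Defaults mirror the reference architecture: 12-step input sequences of 9
#' channels feeding 3 stacked vanilla (tanh) recurrent layers and 2 linear
#' layers, all 64 units wide, trained with Adam at learning rate 1e-3 in
#' batches of 64, predicting glucose 6 steps (30 minutes) ahead. Epoch count
#' and stopping rule are package choices: early stopping on validation RMSE
#' with patience 10, at most 100 epochs.
#'
#' @param seq_len input window length in samples.
#' @param input_channels number of feature channels.
#' @param rnn_layers,linear_layers,hidden architecture sizes.
#' @param batch_size,learning_rate optimizer settings.
#' @param horizon forecast lead in samples (6 x 5 min = 30 min).
#' @param max_epochs,patience early-stopping policy.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @export
model_config <- function(seq_len = 12L, input_channels = 9L, rnn_layers = 3L,
                         linear_layers = 2L, hidden = 64L, batch_size = 64L,
                         learning_rate = 1e-3, horizon = 6L,
                         max_epochs = 100L, patience = 10L, seed = 1L) {
  cfg <- list(seq_len = as.integer(seq_len),
              input_channels = as.integer(input_channels),
              rnn_layers = as.integer(rnn_layers),
              linear_layers = as.integer(linear_layers),
              hidden = as.integer(hidden),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              horizon = as.integer(horizon),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              seed = as.integer(seed))
  stopifnot(cfg$seq_len >= 1, cfg$rnn_layers >= 1, cfg$hidden >= 1,
            cfg$horizon >= 1, cfg$linear_layers == 2L)
  structure(cfg, class = "model_config")
}

#' Build supervised forecasting windows from feature matrices
#'
#' Each window is the transformed 12 x 9 feature block ending at a
#' feature-valid row t, paired with the transformed glucose value 6 steps
#' later in the same segment. No window crosses a segment boundary and all
#' 12 input rows must be feature-valid, so a segment of length L yields
#' max(0, L - 28) windows (11 warm-up rows + 12-row window + 6-step horizon).
#'
#' @param feature_list list of `feature_matrix` objects, one per segment
#'   (only usable segments should be passed).
#' @param params fitted `transform_params`.
#' @param config a [model_config()].
#' @return A `window_set`: list with `inputs` (n x 12 x 9 array, transformed),
#'   `targets` (transformed glucose, length n), `targets_mgdl` (raw mg/dL),
#'   `last_glucose` (raw mg/dL at each window end, for the persistence
#'   baseline), `end_index`, `target_index`, `segment`.
#' @export
make_windows <- function(feature_list, params, config = model_config()) {
  if (inherits(feature_list, "data.frame")) feature_list <- list(feature_list)
  W <- config$seq_len; H <- config$horizon
  inputs <- list(); targets <- list(); targets_raw <- list()
  lastg <- list(); endi <- list(); tgti <- list(); segid <- list()
  for (s in seq_along(feature_list)) {
    fm <- feature_list[[s]]
    L <- nrow(fm)
    lo <- 2L * W - 1L                          # rows 1..(W-1) are warm-up
    hi <- L - H
    if (hi < lo) next
    ends <- lo:hi
    X <- apply_transform(fm, params)
    z <- transform_target(fm$glucose, params)
    arr <- array(NA_real_, c(length(ends), W, ncol(X)))
    for (k in seq_along(ends)) {
      arr[k, , ] <- X[(ends[k] - W + 1):ends[k], , drop = FALSE]
    }
    inputs[[length(inputs) + 1]] <- arr
    targets[[length(targets) + 1]] <- z[ends + H]
    targets_raw[[length(targets_raw) + 1]] <- fm$glucose[ends + H]
    lastg[[length(lastg) + 1]] <- fm$glucose[ends]
    endi[[length(endi) + 1]] <- ends
    tgti[[length(tgti) + 1]] <- ends + H
    segid[[length(segid) + 1]] <- rep(s, length(ends))
  }
  if (length(inputs) == 0) {
    inputs_arr <- array(0, c(0, W, config$input_channels))
  } else {
    inputs_arr <- do.call(abind_1, inputs)
  }
  structure(list(
    inputs = inputs_arr,
    targets = unlist(targets) %||% numeric(0),
    targets_mgdl = unlist(targets_raw) %||% numeric(0),
    last_glucose = unlist(lastg) %||% numeric(0),
    end_index = unlist(endi) %||% integer(0),
    target_index = unlist(tgti) %||% integer(0),
    segment = unlist(segid) %||% integer(0),
    config = config
  ), class = "window_set")
}

# bind 3-d arrays along the first dimension (base R, no abind dependency)
abind_1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], 1L)), d[2], d[3]))
  at <- 0
  for (p in parts) {
    np <- dim(p)[1]
    if (np > 0) out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d x %d, horizon %d steps\n",
              n_windows(x), dim(x$inputs)[2], dim(x$inputs)[3],
              x$config$horizon))
  invisible(x)
}

#' @rdname make_windows
#' @param windows a `window_set`.
#' @export
n_windows <- function(windows) dim(windows$inputs)[1]

#' Persistence (naive last-value) baseline forecast
#'
#' Predicts that glucose 30 minutes ahead equals the last observed value of
#' the window — the standard skill reference for CGM forecasting.
#'
#' @param windows a `window_set`.
#' @return Numeric vector of forecasts in mg/dL.
#' @export
persistence_baseline <- function(windows) {
  windows$last_glucose
}

## ---- recurrent network -----------------------------------------------------

#' Build the recurrent forecaster
#'
#' A stack of `rnn_layers` vanilla recurrent layers with tanh activation and
#' `hidden` units reads the `seq_len` x `input_channels` window; the final
#' hidden state feeds linear(hidden -> hidden) + ReLU and a last
#' linear(hidden -> 1) regression head. Weights are initialized uniformly on
#' \[-1/sqrt(hidden), 1/sqrt(hidden)\] under the config seed, so two models
#' built from the same config are identical.
#'
#' @param config a [model_config()].
#' @return An `rnn_model` (list of weight matrices plus the config).
#' @export
build_model <- function(config = model_config()) {
  h <- config$hidden
  bound <- 1 / sqrt(h)
  with_seed(config$seed, {
    layers <- vector("list", config$rnn_layers)
    for (l in seq_len(config$rnn_layers)) {
      din <- if (l == 1) config$input_channels else h
      layers[[l]] <- list(
        W_ih = matrix(stats::runif(h * din, -bound, bound), h, din),
        W_hh = matrix(stats::runif(h * h, -bound, bound), h, h),
        b = stats::runif(h, -bound, bound))
    }
    fc1 <- list(W = matrix(stats::runif(h * h, -bound, bound), h, h),
                b = stats::runif(h, -bound, bound))
    fc2 <- list(W = matrix(stats::runif(h, -bound, bound), 1, h),
                b = stats::runif(1, -bound, bound))
    structure(list(layers = layers, fc1 = fc1, fc2 = fc2, config = config),
              class = "rnn_model")
  })
}

#' @export
print.rnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<rnn_model> %d RNN layer(s) (tanh, hidden %d) + 2 linear; %d x %d input; %d parameters\n",
    cfg$rnn_layers, cfg$hidden, cfg$seq_len, cfg$input_channels,
    count_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Closed form for the configured shapes:
#' `(h*c + h^2 + h) + (L-1)*(2h^2 + h) + (h^2 + h) + (h + 1)` for hidden
#' size h, c input channels and L recurrent layers.
#' @param model an `rnn_model`.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers,
             function(l) length(l$W_ih) + length(l$W_hh) + length(l$b), 1)) +
    length(model$fc1$W) + length(model$fc1$b) +
    length(model$fc2$W) + length(model$fc2$b)
}

#' Forward pass of the recurrent forecaster
#'
#' Runs a batch through the network in transformed space. Mostly useful for
#' inspection and testing; end users should call [predict_glucose()], which
#' also inverts the target transform.
#'
#' @param model an `rnn_model`.
#' @param X numeric array, batch x seq_len x channels.
#' @param keep keep per-timestep hidden states (needed for
#'   backpropagation through time).
#' @return List with `yhat` (length-batch predictions, transformed space)
#'   and, when `keep = TRUE`, the cached hidden states.
#' @export
rnn_forward <- function(model, X, keep = FALSE) {
  cfg <- model$config
  B <- dim(X)[1]; TT <- dim(X)[2]
  nl <- cfg$rnn_layers; h <- cfg$hidden
  H <- if (keep) vector("list", nl)
  Hprev <- vector("list", nl)
  for (l in seq_len(nl)) {
    Hprev[[l]] <- matrix(0, B, h)
    if (keep) H[[l]] <- vector("list", TT)
  }
  for (t in seq_len(TT)) {
    inp <- X[, t, , drop = FALSE]
    dim(inp) <- c(B, dim(X)[3])
    for (l in seq_len(nl)) {
      a <- inp %*% t(model$layers[[l]]$W_ih) +
        Hprev[[l]] %*% t(model$layers[[l]]$W_hh)
      a <- sweep(a, 2, model$layers[[l]]$b, "+")
      Hl <- tanh(a)
      Hprev[[l]] <- Hl
      if (keep) H[[l]][[t]] <- Hl
      inp <- Hl
    }
  }
  hT <- Hprev[[nl]]
  z1 <- sweep(hT %*% t(model$fc1$W), 2, model$fc1$b, "+")
  r <- pmax(z1, 0)
  yhat <- as.numeric(r %*% t(model$fc2$W)) + model$fc2$b
  if (keep) list(yhat = yhat, H = H, z1 = z1, r = r) else list(yhat = yhat)
}

# Gradients of mean((yhat - y)^2) w.r.t. every parameter, by backpropagation
# through time. Returns a list shaped like the model's parameters.
rnn_gradients <- function(model, X, y, fw = NULL) {
  cfg <- model$config
  B <- dim(X)[1]; TT <- dim(X)[2]; nl <- cfg$rnn_layers; h <- cfg$hidden
  if (is.null(fw)) fw <- rnn_forward(model, X, keep = TRUE)
  dy <- matrix(2 * (fw$yhat - y) / B, B, 1)

  g <- list(layers = lapply(model$layers, function(l)
    list(W_ih = l$W_ih * 0, W_hh = l$W_hh * 0, b = l$b * 0)),
    fc1 = list(W = model$fc1$W * 0, b = model$fc1$b * 0),
    fc2 = list(W = model$fc2$W * 0, b = model$fc2$b * 0))

  g$fc2$W <- t(dy) %*% fw$r
  g$fc2$b <- sum(dy)
  dr <- dy %*% model$fc2$W
  dz1 <- dr * (fw$z1 > 0)
  hT <- fw$H[[nl]][[TT]]
  g$fc1$W <- t(dz1) %*% hT
  g$fc1$b <- colSums(dz1)

  # dH[[t]] for the layer currently being processed, top down
  dH <- vector("list", TT)
  for (t in seq_len(TT)) dH[[t]] <- matrix(0, B, h)
  dH[[TT]] <- dz1 %*% model$fc1$W

  for (l in rev(seq_len(nl))) {
    Wl <- model$layers[[l]]
    dX_below <- if (l > 1) lapply(seq_len(TT), function(t) matrix(0, B, h))
    dcarry <- matrix(0, B, h)
    for (t in rev(seq_len(TT))) {
      da <- (dH[[t]] + dcarry) * (1 - fw$H[[l]][[t]]^2)
      inp <- if (l == 1) {
        xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, dim(X)[3]); xt
      } else fw$H[[l - 1]][[t]]
      hprev <- if (t == 1) matrix(0, B, h) else fw$H[[l]][[t - 1]]
      g$layers[[l]]$W_ih <- g$layers[[l]]$W_ih + t(da) %*% inp
      g$layers[[l]]$W_hh <- g$layers[[l]]$W_hh + t(da) %*% hprev
      g$layers[[l]]$b <- g$layers[[l]]$b + colSums(da)
      dcarry <- da %*% Wl$W_hh
      if (l > 1) dX_below[[t]] <- da %*% Wl$W_ih
    }
    if (l > 1) dH <- dX_below
  }
  g
}

# flatten/unflatten parameters for the optimizer
params_to_vec <- function(p) {
  unlist(list(lapply(p$layers, function(l) c(l$W_ih, l$W_hh, l$b)),
              c(p$fc1$W, p$fc1$b), c(p$fc2$W, p$fc2$b)), use.names = FALSE)
}

vec_to_params <- function(v, template) {
  at <- 0
  take <- function(n) { out <- v[at + seq_len(n)]; at <<- at + n; out }
  for (l in seq_along(template$layers)) {
    tl <- template$layers[[l]]
    template$layers[[l]]$W_ih <- matrix(take(length(tl$W_ih)), nrow(tl$W_ih))
    template$layers[[l]]$W_hh <- matrix(take(length(tl$W_hh)), nrow(tl$W_hh))
    template$layers[[l]]$b <- take(length(tl$b))
  }
  template$fc1$W <- matrix(take(length(template$fc1$W)), nrow(template$fc1$W))
  template$fc1$b <- take(length(template$fc1$b))
  template$fc2$W <- matrix(take(length(template$fc2$W)), nrow(template$fc2$W))
  template$fc2$b <- take(length(template$fc2$b))
  template
}

#' Train the forecaster on a window set
#'
#' Minimizes mean-squared error in transformed target space with Adam
#' (lr from the config, beta1 0.9, beta2 0.999). The window set is split
#' chronologically — the last 20% of windows form the validation set — and
#' training stops early when validation RMSE has not improved for
#' `config$patience` epochs; the best-epoch weights are returned. Batch
#' order is reshuffled each epoch under the config seed, so identical
#' seeded runs are bitwise identical.
#'
#' @param windows a `window_set` with at least one window.
#' @param config a [model_config()].
#' @param quiet suppress per-epoch progress.
#' @return A `train_result`: list with `model` (best-epoch `rnn_model`),
#'   `history` (per-epoch train loss and validation RMSE, transformed
#'   space), `best_epoch`, `best_val_rmse`.
#' @export
train_model <- function(windows, config = model_config(), quiet = TRUE) {
  n <- n_windows(windows)
  if (n < 1) stop("empty window set")
  n_val <- max(1L, floor(0.2 * n))
  if (n_val >= n) n_val <- n - 1L
  idx_train <- seq_len(n - n_val)
  idx_val <- if (n_val > 0) (n - n_val + 1L):n else integer(0)

  model <- build_model(config)
  vec <- params_to_vec(model)
  m <- numeric(length(vec)); v <- numeric(length(vec))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0

  Xval <- windows$inputs[idx_val, , , drop = FALSE]
  yval <- windows$targets[idx_val]

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_rmse = numeric())
  best_vec <- vec; best_rmse <- Inf; best_epoch <- 0L; stall <- 0L

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(idx_train)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        Xb <- windows$inputs[b, , , drop = FALSE]
        yb <- windows$targets[b]
        fw <- rnn_forward(model, Xb, keep = TRUE)
        ep_loss <- ep_loss + sum((fw$yhat - yb)^2)
        gr <- rnn_gradients(model, Xb, yb, fw)
        gvec <- params_to_vec(gr)
        step <- step + 1
        m <- beta1 * m + (1 - beta1) * gvec
        v <- beta2 * v + (1 - beta2) * gvec^2
        mhat <- m / (1 - beta1^step)
        vhat <- v / (1 - beta2^step)
        vec <- vec - config$learning_rate * mhat / (sqrt(vhat) + eps)
        model <- vec_to_params(vec, model)
      }
      ep_loss <- ep_loss / length(idx_train)
      val_rmse <- if (length(idx_val)) {
        sqrt(mean((rnn_forward(model, Xval)$yhat - yval)^2))
      } else sqrt(ep_loss)
      history[epoch, ] <- list(epoch, ep_loss, val_rmse)
      if (!quiet) {
        message(sprintf("epoch %3d  train MSE %.5f  val RMSE %.5f",
                        epoch, ep_loss, val_rmse))
      }
      if (val_rmse < best_rmse - 1e-9) {
        best_rmse <- val_rmse; best_vec <- vec; best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })

  structure(list(model = vec_to_params(best_vec, model), history = history,
                 best_epoch = best_epoch, best_val_rmse = best_rmse),
            class = "train_result")
}

#' Forecast glucose for a window set
#'
#' Runs the trained model and inverts the target transform, returning
#' forecasts in mg/dL (finite and positive by construction of the inverse
#' log transform).
#'
#' @param model an `rnn_model`.
#' @param windows a `window_set` built with the same channel contract.
#' @param params the `transform_params` the model was trained with.
#' @return Numeric vector of forecasts in mg/dL, one per window.
#' @export
predict_glucose <- function(model, windows, params) {
  stopifnot(inherits(model, "rnn_model"), inherits(windows, "window_set"))
  if (dim(windows$inputs)[3] != model$config$input_channels) {
    stop("window channel count does not match the model's input channels")
  }
  if (n_windows(windows) == 0) return(numeric(0))
  z <- rnn_forward(model, windows$inputs)$yhat
  invert_target(z, params)
}
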