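cfg_small <- model_config(max_epochs = 5, seed = 3)

make_fixture_windows <- function(days = 2, seed = 7, config = cfg_small) {
  tr <- sim_small(days = days, seed = seed)
  fm <- derive_features(tr)
  params <- fit_transform(fm)
  list(windows = make_windows(list(fm), params, config), params = params,
       fm = fm)
}

test_that("window counts follow max(0, L - 28) for every segment length", {
  tr <- sim_small(days = 2, seed = 1)
  fm_full <- derive_features(tr)
  params <- fit_transform(fm_full)
  cfg <- model_config()

  for (L in c(1, 5, 12, 28, 29, 30, 100, 300)) {
    seg <- gs(tr$values[seq_len(L)])
    fm <- suppressWarnings(derive_features(seg))
    w <- make_windows(list(fm), params, cfg)
    # brute-force enumeration of admissible (end, target) pairs
    want <- sum(vapply(seq_len(L), function(t) {
      t >= 23 && t + 6 <= L
    }, TRUE))
    expect_equal(n_windows(w), want, info = paste("L =", L))
    expect_equal(n_windows(w), max(0, L - 28))
  }

  # minimal case: rows 12..23 feed the window, target row 29
  seg29 <- gs(tr$values[1:29])
  w29 <- make_windows(list(derive_features(seg29)), params, cfg)
  expect_equal(n_windows(w29), 1)
  expect_equal(w29$end_index, 23)
  expect_equal(w29$target_index, 29)
})

test_that("windows never span segments and always lead their target by 6 steps", {
  fx <- make_fixture_windows(days = 2)
  w <- fx$windows
  expect_equal(w$target_index - w$end_index, rep(6L, n_windows(w)))

  # two segments: window indices stay within each segment
  tr <- sim_small(days = 2, seed = 2)
  f1 <- derive_features(gs(tr$values[1:60]))
  f2 <- derive_features(gs(tr$values[101:200]))
  params <- fit_transform(rbind(f1, f2))
  w2 <- make_windows(list(f1, f2), params, model_config())
  expect_equal(n_windows(w2), (60 - 28) + (100 - 28))
  expect_true(all(w2$target_index[w2$segment == 1] <= 60))
  expect_true(all(w2$target_index[w2$segment == 2] <= 100))

  # inputs hold the transformed features of rows end-11..end
  X <- apply_transform(f1, params)
  k <- 5
  expect_equal(w2$inputs[k, , ],
               unname(X[(w2$end_index[k] - 11):w2$end_index[k], ]))
})

test_that("model construction is seeded, shaped, and countable in closed form", {
  cfg <- model_config(seed = 11)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  set.seed(1); X <- array(rnorm(7 * 12 * 9), c(7, 12, 9))
  expect_equal(rnn_forward(m1, X)$yhat, rnn_forward(m2, X)$yhat,
               tolerance = 1e-12)
  expect_length(rnn_forward(m1, X)$yhat, 7)

  # closed-form parameter count for h=64, c=9, 3 recurrent layers
  h <- 64; c_ <- 9
  want <- (h * c_ + h * h + h) + 2 * (2 * h * h + h) + (h * h + h) + (h + 1)
  expect_equal(count_parameters(m1), want)

  # zero weights -> output is the final bias
  m0 <- m1
  m0 <- cgmforecast:::vec_to_params(rep(0, count_parameters(m1)), m0)
  m0$fc2$b <- 1.25
  expect_equal(rnn_forward(m0, X)$yhat, rep(1.25, 7))
})

test_that("backpropagation matches numerical finite differences", {
  cfg <- model_config(seq_len = 4, input_channels = 3, hidden = 5,
                      rnn_layers = 2, seed = 2)
  m <- build_model(cfg)
  set.seed(5)
  X <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
  y <- rnorm(3)
  gvec <- cgmforecast:::params_to_vec(cgmforecast:::rnn_gradients(m, X, y))
  v <- cgmforecast:::params_to_vec(m)
  loss_at <- function(v) {
    mean((rnn_forward(cgmforecast:::vec_to_params(v, m), X)$yhat - y)^2)
  }
  num <- vapply(seq_along(v), function(i) {
    up <- v; up[i] <- up[i] + 1e-6
    dn <- v; dn[i] <- dn[i] - 1e-6
    (loss_at(up) - loss_at(dn)) / 2e-6
  }, 1.0)
  expect_lt(max(abs(num - gvec)), 1e-6)
})

test_that("training reduces loss deterministically and beats persistence", {
  fx <- make_fixture_windows(days = 4, seed = 42,
                             config = model_config(max_epochs = 12, seed = 3))
  cfg <- model_config(max_epochs = 12, seed = 3)
  r1 <- train_model(fx$windows, cfg)
  expect_lte(min(r1$history$train_loss), r1$history$train_loss[1])

  r2 <- train_model(fx$windows, cfg)
  expect_identical(r1$best_val_rmse, r2$best_val_rmse)
  expect_identical(cgmforecast:::params_to_vec(r1$model),
                   cgmforecast:::params_to_vec(r2$model))

  fc <- predict_glucose(r1$model, fx$windows, fx$params)
  expect_length(fc, n_windows(fx$windows))
  expect_true(all(is.finite(fc) & fc > 0))
  rmse_model <- sqrt(mean((fc - fx$windows$targets_mgdl)^2))
  rmse_pers <- sqrt(mean((persistence_baseline(fx$windows) -
                            fx$windows$targets_mgdl)^2))
  expect_lt(rmse_model, rmse_pers)

  expect_error(train_model(structure(list(inputs = array(0, c(0, 12, 9))),
                                     class = "window_set"), cfg),
               "empty window set")
})

test_that("persistence baseline is the 6-step-lagged last value", {
  # constant series: zero error
  fmc <- derive_features(gs(rep(120, 40)))
  pc <- fit_transform(fmc)
  wc <- make_windows(list(fmc), pc, model_config())
  expect_equal(persistence_baseline(wc), wc$targets_mgdl)

  # +1/slot ramp: absolute error exactly 6 everywhere
  fmr <- derive_features(gs(100 + (0:49)))
  wr <- make_windows(list(fmr), pc, model_config())
  expect_equal(abs(persistence_baseline(wr) - wr$targets_mgdl),
               rep(6, n_windows(wr)))

  # random series: matches the direct recomputation
  set.seed(3)
  g <- 120 + cumsum(rnorm(80))
  fmx <- derive_features(gs(g))
  wx <- make_windows(list(fmx), pc, model_config())
  expect_equal(persistence_baseline(wx), g[wx$end_index])
})

test_that("prediction validates the channel contract", {
  fx <- make_fixture_windows(days = 2)
  cfg4 <- model_config(input_channels = 4)
  m_bad <- build_model(cfg4)
  expect_error(predict_glucose(m_bad, fx$windows, fx$params),
               "channel count")
})
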