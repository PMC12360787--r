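test_that("parameter accounting matches the closed form at every size", {
  expect_equal(count_parameters(regressor_config()), 198273L)
  expect_equal(count_parameters(regressor_config(hidden_layers = 1,
                                                 hidden_units = 1)), 14L)
  # count is independent of sequence length
  expect_equal(count_parameters(regressor_config(input_size = 62)), 198273L)
  # built weights really hold that many numbers
  m <- build_regressor(regressor_config(hidden_layers = 2, hidden_units = 8))
  n_actual <- sum(vapply(m$weights, length, integer(1)))
  expect_equal(n_actual, count_parameters(m$config))
})

test_that("training converges on a constant-label toy problem", {
  set.seed(1)
  X <- matrix(runif(120 * 31, 1, 1.5), 120, 31)
  ds <- structure(list(inputs = X, labels = rep(7, 120),
                       provenance = data.frame(grid_index = 1:120,
                                               level = "mean"),
                       lags = fx_lags, seed = 1), class = "training_set")
  cfg <- regressor_config(hidden_layers = 2, hidden_units = 12, epochs = 50,
                          batch_size = 32, learning_rate = 5e-3, dropout = 0)
  m <- train_regressor(ds, cfg, seed = 2)
  expect_lt(tail(m$loss_history$validation, 1), 1e-3)
  p <- predict_cbfi(m, X[1:10, ])
  expect_equal(p, rep(7e-6, 10), tolerance = 0.02)
})

test_that("training is reproducible and predictions are pure functions", {
  ds <- fx_small_training_set()
  cfg <- regressor_config(hidden_units = 12, epochs = 15, batch_size = 16,
                          learning_rate = 3e-3)
  m1 <- train_regressor(ds, cfg, seed = 5)
  m2 <- train_regressor(ds, cfg, seed = 5)
  expect_equal(m1$loss_history$train, m2$loss_history$train,
               tolerance = 1e-12)
  p1 <- predict_cbfi(m1, ds$inputs[1:4, ])
  expect_identical(p1, predict_cbfi(m1, ds$inputs[1:4, ]))
  expect_equal(p1[2], predict_cbfi(m1, ds$inputs[2, , drop = FALSE]), tolerance = 1e-10)
})

test_that("shape errors and manifest bookkeeping are enforced", {
  ds <- fx_small_training_set()
  cfg <- regressor_config(hidden_units = 8, epochs = 5, batch_size = 16)
  m <- train_regressor(ds, cfg, seed = 5)
  expect_error(predict_cbfi(m, matrix(1, 2, 30)), "input size")
  expect_length(m$loss_history$train, 5)
  expect_equal(m$data_manifest$n_samples, nrow(ds$inputs))
  expect_equal(m$data_manifest$n_train, floor(0.8 * nrow(ds$inputs)))
})

test_that("regressor archives round-trip through JSON", {
  ds <- fx_small_training_set()
  cfg <- regressor_config(hidden_units = 8, epochs = 3, batch_size = 16)
  m <- train_regressor(ds, cfg, seed = 5)
  path <- tempfile(fileext = ".json")
  save_regressor(m, path)
  m2 <- load_regressor(path)
  expect_equal(suppressWarnings(predict_cbfi(m2, ds$inputs[1:3, ])),
               suppressWarnings(predict_cbfi(m, ds$inputs[1:3, ])),
               tolerance = 1e-12)
  expect_equal(m2$parameter_count, m$parameter_count)
  unlink(path)
})
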