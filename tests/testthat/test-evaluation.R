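test_that("flow-change metrics are exact arithmetic", {
  expect_equal(rcbfi(c(6e-6, 9e-6), 6e-6), c(1, 1.5))
  expect_error(rcbfi(1, 0), "positive")
  # +20% recovered under +25% true change -> 80% sensitivity
  expect_equal(sensitivity(1.2, 1, 7.5e-6, 6e-6), 80)
  expect_equal(sensitivity(1, 1, 7.5e-6, 6e-6), 0)
  expect_error(sensitivity(1, 1, 6e-6, 6e-6), "undefined")
  expect_equal(relative_error(1.2, 1.5), -20)
  expect_equal(relative_error(1.5, 1.5), 0)
  expect_equal(stability_error(1.1, 1), 10)
  expect_equal(stability_error(1, 1), 0)
  # rational inputs stay exact
  expect_identical(sensitivity(3 / 2, 1, 9e-6, 6e-6), 100)
})

test_that("bootstrap mean matches sampling theory", {
  b0 <- bootstrap_mean(rep(5, 100), seed = 1)
  expect_equal(b0$mean, 5)
  expect_equal(b0$lower, 5)
  expect_equal(b0$upper, 5)
  set.seed(2)
  x <- rnorm(1000)
  b <- bootstrap_mean(x, n_resamples = 1000, resample_size = 1000, seed = 3)
  expect_lt(abs(b$mean), 0.1)
  width <- b$upper - b$lower
  expect_equal(width, 2 * 0.6745 * sd(x) / sqrt(1000), tolerance = 0.25)
})

test_that("sensitivity harness emits a structurally complete report", {
  hm <- head_model()
  ens <- run_layered_mc(hm, 5e4, detector = list(rho = 20, half_width = 5),
                        seed = 8, max_path = 600)
  rep <- run_sensitivity_study(ens, model = NULL,
                               estimators = "singleexp",
                               n_reps = 10, seed = 4)
  expect_s3_class(rep, "sensitivity_report")
  expect_equal(nrow(rep$cells), 8)
  expect_setequal(unique(rep$cells$layer), c("brain", "scalp"))
  expect_setequal(rep$cells$multiplier, rep(c(0.5, 0.75, 1.25, 1.5), 2))
  expect_true(all(is.finite(rep$cells$S)))
  expect_true(all(rep$cells$S_lo <= rep$cells$S_hi))
  expect_equal(rep$summary$brain_S,
               mean(rep$cells$S[rep$cells$layer == "brain"]))
  # brain cells respond far more than scalp cells even for this estimator
  expect_gt(rep$summary$brain_S, abs(rep$summary$scalp_S))
})

test_that("stability sweep marks the reference group as exact zero", {
  ds <- fx_small_training_set()
  cfg <- regressor_config(hidden_units = 12, epochs = 40, batch_size = 16,
                          learning_rate = 5e-3)
  m <- train_regressor(ds, cfg, seed = 5)
  cells <- run_stability_sweep(
    m, estimators = "dl", n_photons = 2e4, n_reps = 3,
    detector = list(rho = 15, half_width = 5), seed = 6,
    param_grids = list(brain_mua = c(0.010, 0.015), Lscalp = c(3, 4)))
  expect_equal(nrow(cells), 4)
  ref <- cells[cells$reference, ]
  expect_equal(nrow(ref), 2)
  expect_equal(ref$E_cbfi, rep(0, 2))
  expect_equal(ref$E_rcbfi, rep(0, 2))
  expect_true(all(is.finite(cells$E_cbfi)))
})
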