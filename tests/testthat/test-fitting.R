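test_that("single-exponential fit recovers its own model to 4 significant figures", {
  tau <- fx_lags
  tc <- 20e-6
  y <- 1 + 0.5 * exp(-2 * tau / tc)
  fit <- fit_single_exponential(y, lags = tau)
  expect_equal(fit$a, 1, tolerance = 1e-4)
  expect_equal(fit$b, 0.5, tolerance = 1e-4)
  expect_equal(fit$c, 1e5, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-12)
  expect_equal(decorrelation_speed(fit), 5e4, tolerance = 1e-4)
})

test_that("degenerate inputs raise fit errors", {
  expect_error(fit_single_exponential(rep(1.2, 31), lags = fx_lags),
               "degenerate")
  expect_error(fit_single_exponential(c(1, 1.1), lags = c(1e-6, 2e-6)),
               "at least 3")
})

test_that("relative decorrelation-speed changes are ratio- and scale-invariant", {
  tau <- fx_lags
  f1 <- fit_single_exponential(1 + 0.5 * exp(-1e5 * tau), lags = tau)
  f2 <- fit_single_exponential(1 + 0.5 * exp(-1.5e5 * tau), lags = tau)
  expect_equal(decorrelation_speed(f2) / decorrelation_speed(f1), 1.5,
               tolerance = 1e-6)
  # min-max scaling before fitting leaves relative speed changes unchanged
  med <- fx_medium()
  c1 <- g2_curve(fx_medium(Db_brain = 4e-6, Db_extra = 4e-7), fx_lags)
  c2 <- g2_curve(fx_medium(Db_brain = 8e-6, Db_extra = 8e-7), fx_lags)
  raw_ratio <- decorrelation_speed(fit_single_exponential(c1)) /
    decorrelation_speed(fit_single_exponential(c2))
  sc_ratio <- decorrelation_speed(fit_single_exponential(scale_acf(c1))) /
    decorrelation_speed(fit_single_exponential(scale_acf(c2)))
  expect_equal(sc_ratio, raw_ratio, tolerance = 1e-3)
})

test_that("two-layer inversion recovers generating Db on noiseless curves", {
  set.seed(21)
  for (i in 1:4) {
    Db_brain <- runif(1, 2e-6, 3e-5)
    frac <- runif(1, 0.05, 0.3)
    med <- fx_medium(Db_extra = frac * Db_brain, Db_brain = Db_brain)
    curve <- g2_curve(med, fx_lags)
    fit <- fit_two_layer(curve, med)
    expect_true(fit$converged)
    expect_lt(abs(fit$Db_brain - Db_brain) / Db_brain, 1e-3)
    expect_lt(abs(fit$Db_extra - frac * Db_brain) / (frac * Db_brain), 1e-3)
  }
})

test_that("two-layer fit initialized at the truth stays there", {
  med <- fx_medium(Db_extra = 1.05e-6, Db_brain = 6e-6)
  curve <- g2_curve(med, fx_lags)
  fit <- fit_two_layer(curve, med, init = c(1.05e-6, 6e-6))
  expect_lt(fit$objective, 1e-16)
  expect_true(fit$converged)
})
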