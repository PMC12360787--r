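test_that("lag grid arithmetic matches the SPAD correlator settings", {
  g <- lag_grid(31, 1.28e-6)
  expect_length(g, 31)
  expect_equal(g[1], 1.28e-6)
  expect_equal(g[31], 39.68e-6)
  expect_equal(lag_grid(2, 1), c(1, 2))
  expect_equal(signif(4096 * 1.28e-6, 3), 5.24e-3)
  expect_error(lag_grid(31, -1), "positive")
})

test_that("medium constructor derives the boundary constants consistently", {
  med <- fx_medium()
  expect_equal(med$k0, 2 * pi * 1.4 / (785e-6))
  expect_equal(med$z0, 1 / (0.019 + 0.86), tolerance = 1e-12)
  expect_equal(med$z0, 1.1377, tolerance = 1e-4)
  expect_equal(med$zb, 2 * med$D1 * (1 + med$Reff) / (1 - med$Reff))
  # standard tissue index gives the standard effective reflection value
  expect_equal(effective_reflection(1.4), 0.493, tolerance = 0.01)
  expect_equal(effective_reflection(1), 0)
})

test_that("Fourier kernel is finite, real and static at tau = 0", {
  med <- fx_medium()
  s <- seq(0.01, 20, length.out = 50)
  k <- g1_tilde_twolayer(s, 0, med)
  expect_true(all(is.finite(k)))
  # tau = 0 kills the dynamic terms: any Db gives the same static kernel
  med2 <- fx_medium(Db_extra = 0, Db_brain = 0)
  expect_equal(k, g1_tilde_twolayer(s, 0, med2), tolerance = 1e-14)
  # identical layers reduce to the semi-infinite Fourier kernel for all s
  mi <- fx_identical_medium(0.02, 1.21, 6e-6)
  D <- 1 / (3 * 1.21)
  a <- sqrt(s^2 + (0.02 + 2 * 1.21 * mi$k0^2 * 6e-6 * 1e-5) / D)
  semi <- (exp(-a * mi$z0) - exp(-a * (mi$z0 + 2 * mi$zb))) / (2 * D * a)
  expect_equal(g1_tilde_twolayer(s, 1e-5, mi), semi, tolerance = 1e-12)
})

test_that("two-layer g1 is normalized, monotone and quadrature-robust", {
  med <- fx_medium(Db_extra = 2.5e-5 * 0.175, Db_brain = 2.5e-5)
  g1 <- g1_twolayer(med, fx_lags)
  expect_true(all(g1 > 0))
  expect_true(all(diff(g1) < 0))
  expect_equal(g1_twolayer(med, 0), 1, tolerance = 1e-10)
  # halving the tolerance must not move any value appreciably
  expect_equal(g1_twolayer(med, fx_lags, rel_tol = 5e-9), g1,
               tolerance = 1e-6)
})

test_that("identical layers reproduce the semi-infinite closed form", {
  set.seed(7)
  for (i in 1:5) {
    mua <- runif(1, 0.005, 0.025)
    musp <- runif(1, 0.9, 1.3)
    Db <- runif(1, 5e-7, 5e-5)
    med <- fx_identical_medium(mua, musp, Db, l = sample(8:15, 1))
    g1 <- g1_twolayer(med, fx_lags)
    gs <- g1_semiinfinite(layer_optics(mua, musp, Db), 35, fx_lags)
    expect_lt(max(abs(g1 - gs) / pmax(gs, 1e-12)), 1e-5)
  }
})

test_that("semi-infinite closed form has its exact scaling identities", {
  opt <- layer_optics(0.02, 1.21, 6e-6)
  expect_equal(g1_semiinfinite(opt, 35, 0), 1)
  expect_equal(g1_semiinfinite(layer_optics(0.02, 1.21, 0), 35, fx_lags),
               rep(1, 31))
  # K^2(tau) - K^2(0) depends on Db and tau only through their product, so
  # doubling Db is exactly equivalent to doubling every lag
  opt2 <- layer_optics(0.02, 1.21, 1.2e-5)
  expect_equal(g1_semiinfinite(opt2, 35, fx_lags),
               g1_semiinfinite(opt, 35, 2 * fx_lags), tolerance = 1e-12)
})

test_that("large extracerebral thickness converges to layer-1 semi-infinite", {
  med <- two_layer_medium(
    layer1 = layer_optics(0.019, 0.86, 1e-6, thickness = 55),
    layer2 = layer_optics(0.02, 1.21, 3e-5), rho = 35)
  g1 <- g1_twolayer(med, fx_lags)
  gs <- g1_semiinfinite(layer_optics(0.019, 0.86, 1e-6), 35, fx_lags)
  expect_lt(max(abs(g1 - gs)), 1e-6)
})

test_that("Siegert relation and g2 curves respect the coherence bounds", {
  expect_equal(g2_from_g1(1, 0.5), 1.5)
  expect_equal(g2_from_g1(0, 0.5), 1.0)
  expect_equal(g2_from_g1(0.6, 0.5), 1.18)
  med <- fx_medium()
  g2 <- g2_curve(med, fx_lags)
  expect_s3_class(g2, "acf_curve")
  expect_identical(g2$kind, "g2")
  expect_true(all(g2$values > 1 & g2$values <= 1.5 + 1e-12))
  expect_true(all(diff(g2$values) < 0))
  expect_equal(g2_from_g1(g1_twolayer(med, 0), med$beta), 1.5,
               tolerance = 1e-10)
})

test_that("higher brain flow lowers the whole g2 curve pointwise", {
  g_prev <- NULL
  for (Db in c(5e-7, 5e-6, 5e-5)) {
    g <- g2_curve(fx_medium(Db_brain = Db, Db_extra = 0.175 * Db), fx_lags)
    if (!is.null(g_prev)) expect_true(all(g$values < g_prev$values))
    g_prev <- g
  }
})
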