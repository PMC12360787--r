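# small homogeneous ensemble shared across blocks
mc_env <- new.env()
mc_homog <- function() {
  if (is.null(mc_env$ens)) {
    hm <- head_model(data.frame(name = "tissue", thickness = Inf,
                                mua = 0.02, musp = 1.2, Db = 6e-6),
                     g_anisotropy = 0.89)
    mc_env$hm <- hm
    mc_env$ens <- run_layered_mc(hm, 2e5,
                                 detector = list(rho = 12.5, half_width = 2.5),
                                 seed = 3, max_path = 600)
  }
  mc_env$ens
}

test_that("ensembles are reproducible and satisfy the tally invariants", {
  hm <- head_model()
  e1 <- run_layered_mc(hm, 2000, detector = list(rho = 15, half_width = 5),
                       seed = 11, max_path = 600)
  e2 <- run_layered_mc(hm, 2000, detector = list(rho = 15, half_width = 5),
                       seed = 11, max_path = 600)
  expect_identical(e1$L, e2$L)
  expect_identical(e1$Y, e2$Y)
  expect_lte(e1$n_detected, e1$n_launched)
  expect_true(all(e1$L >= 0) && all(e1$Y >= 0))
  # no momentum transfer can accrue in a layer never visited
  expect_true(all(e1$Y[e1$L == 0] == 0))
  expect_true(all(e1$exit_radius >= 10 & e1$exit_radius <= 20))
})

test_that("ensemble g1 reproduces the semi-infinite solution within MC error", {
  ens <- mc_homog()
  expect_gt(ens$n_detected, 5000)
  g1 <- g1_from_records(ens, lags = fx_lags)
  w <- exp(-0.02 * rowSums(ens$L))
  oracle <- vapply(fx_lags, function(tt)
    sum(w * g1_semiinfinite(layer_optics(0.02, 1.2, 6e-6),
                            ens$exit_radius, tt)) / sum(w), numeric(1))
  sel <- g1$values > 0.1
  expect_lt(max(abs(g1$values - oracle)[sel]), 0.02)
})

test_that("g1 from records is exact in its closed-form limits", {
  ens <- mc_homog()
  expect_equal(g1_from_records(ens, lags = 1e-9)$values, 1, tolerance = 1e-3)
  g_static <- g1_from_records(ens, Db = 0, lags = fx_lags)
  expect_equal(g_static$values, rep(1, 31))
  # single-photon ensemble: g1(tau) = exp(-2 k0^2 Y Db tau) exactly
  single <- ens
  single$L <- ens$L[1, , drop = FALSE]
  single$Y <- ens$Y[1, , drop = FALSE]
  g_one <- g1_from_records(single, lags = fx_lags)
  k0 <- ens$head$k0
  expect_equal(g_one$values,
               exp(-2 * k0^2 * ens$Y[1, 1] * 6e-6 * fx_lags),
               tolerance = 1e-12)
})

test_that("transport and dynamics separate: same ensemble, any Db", {
  ens <- mc_homog()
  a <- g1_from_records(ens, Db = 3e-6, lags = fx_lags)$values
  b <- g1_from_records(ens, Db = 3e-6, lags = fx_lags)$values
  expect_identical(a, b)
  cc <- g1_from_records(ens, Db = 9e-6, lags = fx_lags)$values
  expect_true(all(cc[fx_lags > 0] <= a[fx_lags > 0]))
})

test_that("deep-probing photons at 35 mm traverse scalp and brain", {
  hm <- head_model()
  ens <- run_layered_mc(hm, 3e5, detector = list(rho = 35, half_width = 2.5),
                        seed = 5, max_path = 1000)
  expect_gt(ens$n_detected, 100)
  expect_true(all(ens$L[, "scalp"] > 0))
  expect_gt(mean(ens$L[, "brain"] > 0), 0.9)
  expect_gt(mean(ens$L[, "brain"]), 0)
})

test_that("mc_test_dataset reuses transport and labels perturbations", {
  ens <- mc_homog()
  lv <- default_sigma_profile(fx_lags)
  cells <- mc_test_dataset(ens, list(1, 1.5), n_reps = 3, level = lv,
                           seed = 2, lags = fx_lags)
  expect_length(cells, 2)
  expect_equal(cells[[1]]$Db, 6e-6)
  expect_equal(cells[[2]]$Db, 9e-6)
  expect_equal(dim(cells[[1]]$noisy), c(3, 31))
  # identity perturbation reproduces the baseline clean curve exactly
  base <- g2_from_records(ens, lags = fx_lags)
  expect_identical(cells[[1]]$clean$values, base$values)
})
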