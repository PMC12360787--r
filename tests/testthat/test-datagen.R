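test_that("parameter grid has the documented cardinality and ordering", {
  spec <- grid_spec()
  expect_equal(length(spec$brain_mua), 5)
  expect_equal(length(spec$brain_musp), 5)
  expect_equal(length(spec$thickness), 8)
  expect_equal(length(spec$Db_brain), 100)
  expect_equal(length(spec$fraction), 20)
  # step of the Db axis is 5e-7 (100 inclusive linear steps)
  expect_equal(diff(spec$Db_brain)[1], 5e-7, tolerance = 1e-12)
  small <- grid_spec(brain_mua = c(0.005, 0.01), brain_musp = c(0.9, 1.0),
                     thickness = 8, Db_brain = 5e-7, fraction = 0.05)
  g <- build_parameter_grid(small)
  expect_equal(nrow(g), 4)
  full_first <- build_parameter_grid(
    grid_spec(brain_mua = 0.005, brain_musp = 0.9,
              thickness = 8:9, Db_brain = c(5e-7, 1e-6),
              fraction = c(0.05, 0.3)))
  expect_equal(unlist(full_first[1, c("brain_mua", "brain_musp", "thickness",
                                      "Db_brain", "fraction")]),
               c(brain_mua = 0.005, brain_musp = 0.9, thickness = 8,
                 Db_brain = 5e-7, fraction = 0.05))
  # fraction varies fastest, then Db
  expect_equal(full_first$fraction[1:2], c(0.05, 0.3))
  expect_equal(full_first$Db_brain[c(1, 3)], c(5e-7, 1e-6))
  expect_equal(full_first$Db_extra, full_first$fraction * full_first$Db_brain)
})

test_that("training set counts, labels and determinism", {
  ts <- fx_small_training_set()
  expect_equal(nrow(ts$inputs), 16 * 3)
  expect_true(all(abs(apply(ts$inputs, 1, min) - 1) < 1e-12))
  expect_true(all(abs(apply(ts$inputs, 1, max) - 1.5) < 1e-12))
  # label/provenance round trip
  grid <- build_parameter_grid(
    grid_spec(brain_mua = 0.015, brain_musp = 1.1, thickness = 11,
              Db_brain = seq(2e-6, 2e-5, length.out = 8),
              fraction = c(0.1, 0.2)))
  expect_equal(ts$labels, grid$Db_brain[ts$provenance$grid_index] * 1e6)
  # regeneration is bit-identical under the same seed
  ts2 <- generate_training_set(grid, make_noise_levels(default_sigma_profile()),
                               seed = 42)
  expect_identical(ts$inputs, ts2$inputs)
})

test_that("zero-sigma levels reproduce the deterministic scaled clean curves", {
  spec <- grid_spec(brain_mua = 0.015, brain_musp = 1.1, thickness = 11,
                    Db_brain = c(4e-6, 1e-5), fraction = 0.2)
  grid <- build_parameter_grid(spec)
  zero <- sigma_profile(fx_lags, rep(0, 31))
  ts <- generate_training_set(grid, list(z1 = zero, z2 = zero, z3 = zero),
                              seed = 1)
  expect_equal(nrow(ts$inputs), 6)
  for (i in 1:2) {
    sc <- scale_acf(g2_curve(medium_from_grid(grid, i), fx_lags))$values
    for (k in 1:3) expect_equal(ts$inputs[(i - 1) * 3 + k, ], sc)
  }
})

test_that("pulsatile scenario spans its ranges with a linear scalp ramp", {
  sc <- pulsatile_scenario(500)
  expect_length(sc$Db_brain, 500)
  expect_equal(range(sc$Db_brain), c(3e-6, 9e-6))
  expect_equal(range(sc$Db_scalp), c(5e-7, 1.5e-6))
  expect_equal(diff(sc$Db_scalp), rep(diff(sc$Db_scalp)[1], 499))
  # asymmetric cardiac template: upstroke to systole faster than decay
  peak <- which.max(sc$Db_brain[1:50])
  expect_lt(peak, 25)
})
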