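# shared fixtures, built in code (no stored data)

fx_lags <- lag_grid()

# representative mid-grid two-layer medium (extracerebral over brain)
fx_medium <- function(Db_extra = 1.05e-6, Db_brain = 6e-6, l = 11,
                      brain_mua = 0.015, brain_musp = 1.1) {
  two_layer_medium(
    layer1 = layer_optics(0.019, 0.86, Db_extra, thickness = l),
    layer2 = layer_optics(brain_mua, brain_musp, Db_brain),
    rho = 35, beta = 0.5)
}

# identical-layer medium whose g1 must equal the semi-infinite closed form
fx_identical_medium <- function(mua, musp, Db, l = 10) {
  two_layer_medium(
    layer1 = layer_optics(mua, musp, Db, thickness = l),
    layer2 = layer_optics(mua, musp, Db),
    rho = 35, beta = 0.5)
}

# tiny training set from an n-medium grid (cached per session)
fx_env <- new.env(parent = emptyenv())

fx_small_training_set <- function() {
  if (is.null(fx_env$ts)) {
    spec <- grid_spec(brain_mua = 0.015, brain_musp = 1.1, thickness = 11,
                      Db_brain = seq(2e-6, 2e-5, length.out = 8),
                      fraction = c(0.1, 0.2))
    grid <- build_parameter_grid(spec)
    fx_env$ts <- generate_training_set(
      grid, make_noise_levels(default_sigma_profile()), seed = 42)
  }
  fx_env$ts
}
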