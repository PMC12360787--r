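#' Parameter grid specification for two-layer training curves
#'
#' Defaults reproduce the full training grid: brain absorption 0.005-0.025
#' (step 0.005) 1/mm, brain reduced scattering 0.9-1.3 (step 0.1) 1/mm,
#' extracerebral thickness 8-15 (step 1) mm, brain Db 5e-7..5e-5 mm^2/s in
#' 100 linear steps, and 20 linearly spaced extracerebral-to-brain Db
#' fractions in [0.05, 0.3]; extracerebral optics, separation and coherence
#' factor are fixed. Cardinality 5 x 5 x 8 x 100 x 20 = 400,000.
#'
#' @param brain_mua,brain_musp,thickness,Db_brain,fraction grid axes
#' @param extra_mua,extra_musp fixed extracerebral optics (1/mm)
#' @param rho source-detector separation (mm)
#' @param beta coherence factor
#' @param wavelength wavelength (nm)
#' @param n0 refractive index
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(brain_mua = seq(0.005, 0.025, by = 0.005),
                      brain_musp = seq(0.9, 1.3, by = 0.1),
                      thickness = seq(8, 15, by = 1),
                      Db_brain = seq(5e-7, 5e-5, length.out = 100),
                      fraction = seq(0.05, 0.3, length.out = 20),
                      extra_mua = 0.019, extra_musp = 0.86,
                      rho = 35, beta = 0.5, wavelength = 785, n0 = 1.4) {
  stopifnot(all(Db_brain > 0), all(fraction > 0))
  structure(list(brain_mua = brain_mua, brain_musp = brain_musp,
                 thickness = thickness, Db_brain = Db_brain,
                 fraction = fraction, extra_mua = extra_mua,
                 extra_musp = extra_musp, rho = rho, beta = beta,
                 wavelength = wavelength, n0 = n0),
            class = "grid_spec")
}

#' Reduced grid for fast end-to-end runs
#'
#' A 2 x 2 x 2 x 10 x 4 = 320-medium subset spanning the same ranges as the
#' full grid, intended for complete pipeline runs in minutes.
#'
#' @inheritParams grid_spec
#' @return a `grid_spec`
#' @export
ci_grid_spec <- function(rho = 35, beta = 0.5) {
  grid_spec(brain_mua = c(0.005, 0.025),
            brain_musp = c(0.9, 1.3),
            thickness = c(8, 15),
            Db_brain = seq(5e-7, 5e-5, length.out = 10),
            fraction = seq(0.05, 0.3, length.out = 4),
            rho = rho, beta = beta)
}

#' Enumerate the Cartesian parameter grid
#'
#' Loop order (outermost to innermost): brain mua, brain musp, thickness,
#' Db_brain, fraction -- so the first row is the smallest value of every
#' axis and the fraction axis varies fastest.
#'
#' @param spec a `grid_spec`
#' @return data.frame with one row per medium (columns `brain_mua`,
#'   `brain_musp`, `thickness`, `Db_brain`, `fraction`, `Db_extra`) and the
#'   spec attached as attribute `"spec"`
#' @export
build_parameter_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  g <- expand.grid(fraction = spec$fraction, Db_brain = spec$Db_brain,
                   thickness = spec$thickness, brain_musp = spec$brain_musp,
                   brain_mua = spec$brain_mua,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("brain_mua", "brain_musp", "thickness", "Db_brain", "fraction")]
  g$Db_extra <- g$fraction * g$Db_brain
  rownames(g) <- NULL
  attr(g, "spec") <- spec
  g
}

#' Two-layer medium for one grid row
#'
#' @param grid a grid from [build_parameter_grid()]
#' @param i row index
#' @return a `two_layer_medium`
#' @export
medium_from_grid <- function(grid, i) {
  spec <- attr(grid, "spec")
  r <- grid[i, ]
  two_layer_medium(
    layer1 = layer_optics(spec$extra_mua, spec$extra_musp, r$Db_extra,
                          thickness = r$thickness),
    layer2 = layer_optics(r$brain_mua, r$brain_musp, r$Db_brain),
    rho = spec$rho, wavelength = spec$wavelength, n0 = spec$n0,
    beta = spec$beta)
}

#' Synthesize the paired (noisy curve, CBFi label) training corpus
#'
#' For every grid medium the clean two-layer g2 curve is computed once, and
#' each noise level contributes one scaled noisy sample labelled with
#' Db_brain x 1e6. Samples are ordered medium-major, level-minor, and the
#' whole synthesis is reproducible from `seed`.
#'
#' @param grid a grid from [build_parameter_grid()]
#' @param levels list of `sigma_profile` noise levels (e.g.
#'   [make_noise_levels()] output)
#' @param seed integer seed driving all noise draws
#' @param lags lag grid (seconds)
#' @param verbose report progress every 100 media
#' @return an object of class `training_set`: `inputs` (n x n_lags matrix in
#'   [1, 1.5]), `labels` (Db_brain x 1e6), `provenance` data.frame
#' @export
generate_training_set <- function(grid, levels, seed = 1,
                                  lags = lag_grid(), verbose = FALSE) {
  stopifnot(is.data.frame(grid), length(levels) >= 1L)
  nm <- nrow(grid)
  nlev <- length(levels)
  n <- nm * nlev
  inputs <- matrix(NA_real_, n, length(lags))
  labels <- numeric(n)
  prov <- data.frame(grid_index = rep(seq_len(nm), each = nlev),
                     level = rep(names(levels) %||% seq_len(nlev), nm),
                     stringsAsFactors = FALSE)
  with_seed(seed, {
    k <- 0L
    for (i in seq_len(nm)) {
      med <- medium_from_grid(grid, i)
      clean <- tryCatch(g2_curve(med, lags),
                        error = function(e)
                          stop(sprintf("forward model failed at grid row %d (mua=%g musp=%g l=%g Db=%g frac=%g): %s",
                                       i, grid$brain_mua[i], grid$brain_musp[i],
                                       grid$thickness[i], grid$Db_brain[i],
                                       grid$fraction[i], conditionMessage(e))))
      for (lv in levels) {
        k <- k + 1L
        inputs[k, ] <- add_noise(clean, lv)$values
        labels[k] <- grid$Db_brain[i] * 1e6
      }
      if (verbose && i %% 100 == 0)
        message(sprintf("  %d / %d media", i, nm))
    }
  })
  structure(list(inputs = inputs, labels = labels, provenance = prov,
                 lags = lags, seed = seed), class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set %d samples x %d lags, labels %.3g..%.3g (CBFi x 1e6)>\n",
              nrow(x$inputs), ncol(x$inputs), min(x$labels), max(x$labels)))
  invisible(x)
}

#' Pulsatile brain flow and ramping scalp flow scenario
#'
#' Brain Db follows an asymmetric raised-cosine cardiac template (systolic
#' upstroke over the first 30% of each cycle, slower diastolic decay over
#' the remainder) spanning `brain_range` exactly; scalp Db ramps linearly
#' between the `scalp_ramp` endpoints. With the default 50 samples per
#' cycle, 500 samples cover 10 beats.
#'
#' @param n_samples number of time samples (>= 2)
#' @param brain_range range (mm^2/s) of the pulsatile brain Db
#' @param scalp_ramp endpoints (mm^2/s) of the linear scalp Db ramp
#' @param samples_per_cycle cardiac period in samples
#' @return list with numeric vectors `Db_brain` and `Db_scalp`
#' @export
pulsatile_scenario <- function(n_samples = 500,
                               brain_range = c(3e-6, 9e-6),
                               scalp_ramp = c(5e-7, 1.5e-6),
                               samples_per_cycle = 50) {
  stopifnot(n_samples >= 2, samples_per_cycle >= 4)
  ph <- ((seq_len(n_samples) - 1) %% samples_per_cycle) / samples_per_cycle
  rise <- 0.3
  w <- ifelse(ph < rise,
              0.5 * (1 - cos(pi * ph / rise)),
              0.5 * (1 + cos(pi * (ph - rise) / (1 - rise))))
  # guarantee the stated endpoints are attained exactly
  w <- (w - min(w)) / (max(w) - min(w))
  list(Db_brain = brain_range[1] + diff(brain_range) * w,
       Db_scalp = seq(scalp_ramp[1], scalp_ramp[2], length.out = n_samples))
}
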