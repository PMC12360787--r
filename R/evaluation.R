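#' Relative cerebral blood flow index
#'
#' @param series recovered CBFi values (or decorrelation speeds)
#' @param baseline baseline value (> 0), typically the mean recovery over
#'   baseline replicates
#' @return elementwise ratio series/baseline
#' @export
rcbfi <- function(series, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0)
    stop("baseline must be a positive scalar")
  series / baseline
}

#' Flow-change sensitivity (percent)
#'
#' S = [(CBFi - CBFi0)/CBFi0] / [(Db - Db0)/Db0] x 100. 100% is ideal for
#' brain perturbations, 0% for scalp confounds. For the single-exponential
#' estimator the recovered quantity is the decorrelation speed.
#'
#' @param cbfi recovered value(s) under perturbation
#' @param cbfi0 baseline recovered value
#' @param Db true perturbed Brownian coefficient
#' @param Db0 true baseline Brownian coefficient
#' @return sensitivity in percent (vectorized over `cbfi`)
#' @export
sensitivity <- function(cbfi, cbfi0, Db, Db0) {
  if (cbfi0 == 0 || Db0 == 0 || Db == Db0)
    stop("sensitivity undefined: zero denominator")
  ((cbfi - cbfi0) / cbfi0) / ((Db - Db0) / Db0) * 100
}

#' Percentage error in recovered relative flow
#'
#' eps = (rCBF - rDb)/rDb x 100.
#'
#' @param rCBF recovered relative flow change
#' @param rDb true relative Db change (> 0)
#' @return error in percent
#' @export
relative_error <- function(rCBF, rDb) {
  stopifnot(all(rDb > 0))
  (rCBF - rDb) / rDb * 100
}

#' Stability error against a reference group (percent)
#'
#' E = (p - pref)/pref x 100 for a recovered CBFi or rCBFi.
#'
#' @param p recovered value(s) in a parameter group
#' @param pref recovered value in the reference group (nonzero)
#' @return error in percent
#' @export
stability_error <- function(p, pref) {
  stopifnot(pref != 0)
  (p - pref) / pref * 100
}

#' Bootstrap mean with percentile band
#'
#' Draws `n_resamples` bootstrap means of `resample_size` observations with
#' replacement and returns their mean and the 25th/75th percentiles.
#'
#' @param values nonempty numeric vector
#' @param n_resamples number of bootstrap resamples
#' @param resample_size draws per resample (with replacement)
#' @param seed integer seed
#' @param probs percentile band (default interquartile)
#' @return list with `mean`, `lower`, `upper`, `boot_means`
#' @export
bootstrap_mean <- function(values, n_resamples = 1000, resample_size = 1000,
                           seed = NULL, probs = c(0.25, 0.75)) {
  stopifnot(length(values) >= 1)
  bm <- with_seed(seed, vapply(seq_len(n_resamples), function(i)
    mean(sample(values, resample_size, replace = TRUE)), numeric(1)))
  q <- quantile(bm, probs, names = FALSE)
  list(mean = mean(bm), lower = q[1], upper = q[2], boot_means = bm)
}

# default two-layer prior used when fitting four-layer MC curves: lumped
# extracerebral layer (scalp+skull thickness) with standard extracerebral
# optics, brain layer with the head model's brain optics
default_twolayer_prior <- function(head, rho = 35, beta = 0.5) {
  lay <- head$layers
  brain <- lay[nrow(lay), ]
  l_ec <- sum(lay$thickness[lay$name %in% c("scalp", "skull")])
  if (l_ec == 0) l_ec <- sum(head$layers$thickness[-nrow(lay)])
  two_layer_medium(
    layer1 = layer_optics(0.019, 0.86, 1e-6, thickness = l_ec),
    layer2 = layer_optics(brain$mua, brain$musp, 6e-6),
    rho = rho, wavelength = head$wavelength, n0 = head$n_tissue, beta = beta)
}

# recover per-replicate flow quantities for one estimator from a cell of
# mc_test_dataset output
.recover_cell <- function(cell, estimator, model, prior, sigma_analytic,
                          lags, beta) {
  switch(estimator,
    dl = predict_cbfi(model, cell$noisy),
    singleexp = apply(cell$noisy, 1, function(v)
      decorrelation_speed(fit_single_exponential(v, lags = lags))),
    twolayer = {
      vapply(seq_len(nrow(cell$noisy_raw)), function(i) {
        f <- fit_two_layer(acf_curve(lags, cell$noisy_raw[i, ], kind = "g2"),
                           prior)
        f$Db_brain
      }, numeric(1))
    },
    stop("unknown estimator: ", estimator))
}

#' Perturbation study: brain and scalp flow sensitivity of the estimators
#'
#' Builds a baseline cell and eight perturbation cells (brain and scalp Db
#' at multipliers 0.5, 0.75, 1.25, 1.5 of baseline) from one Monte Carlo
#' ensemble (transport reused across cells), draws `n_reps` noisy replicates
#' per cell, and computes sensitivity and relative-error summaries with
#' bootstrap uncertainty for each estimator. The deep-learning and
#' single-exponential estimators consume SPAD-style noisy scaled curves;
#' the two-layer fit consumes curves with analytic shot noise at the given
#' count rate and integration time.
#'
#' @param ensemble a `detected_ensemble` at the study separation
#' @param model a trained `dcs_regressor` (required for the "dl" estimator)
#' @param level a `sigma_profile` for the SPAD-style noise (mid level)
#' @param estimators subset of c("dl", "singleexp", "twolayer")
#' @param n_reps replicates per cell for the vectorized estimators (dl,
#'   singleexp); the full-scale study uses 1000
#' @param fit_reps replicates per cell for the two-layer fit (each costs a
#'   nonlinear inversion); defaults to `n_reps`
#' @param seed integer seed
#' @param count_rate,t_int analytic-noise parameters for the two-layer fit
#' @param lags lag grid (seconds)
#' @param beta coherence factor
#' @param prior two-layer prior medium; default a lumped extracerebral
#'   layer over the head's brain optics
#' @param brain_layer,scalp_layer indices of the perturbed layers
#' @return an object of class `sensitivity_report`: `cells` data.frame (one
#'   row per estimator x cell with S, eps and bootstrap band) and `summary`
#'   data.frame (per-estimator brain/scalp averages)
#' @export
run_sensitivity_study <- function(ensemble, model = NULL,
                                  level = default_sigma_profile(),
                                  estimators = c("dl", "singleexp", "twolayer"),
                                  n_reps = 50, fit_reps = n_reps, seed = 1,
                                  count_rate = 3300, t_int = 180,
                                  lags = lag_grid(), beta = 0.5,
                                  prior = NULL,
                                  brain_layer = NULL, scalp_layer = 1) {
  stopifnot(inherits(ensemble, "detected_ensemble"))
  if ("dl" %in% estimators && is.null(model))
    stop("the dl estimator needs a trained model")
  nl <- nrow(ensemble$head$layers)
  if (is.null(brain_layer)) brain_layer <- nl
  if (is.null(prior)) prior <- default_twolayer_prior(
    ensemble$head, rho = ensemble$detector$rho, beta = beta)

  mults <- c(0.5, 0.75, 1.25, 1.5)
  cells_def <- list(list(layer = "baseline", multiplier = 1,
                         mult_vec = rep(1, nl)))
  for (m in mults) {
    v <- rep(1, nl); v[brain_layer] <- m
    cells_def <- c(cells_def, list(list(layer = "brain", multiplier = m,
                                        mult_vec = v)))
  }
  for (m in mults) {
    v <- rep(1, nl); v[scalp_layer] <- m
    cells_def <- c(cells_def, list(list(layer = "scalp", multiplier = m,
                                        mult_vec = v)))
  }

  base_Db <- ensemble$head$layers$Db
  data_cells <- mc_test_dataset(ensemble,
                                lapply(cells_def, `[[`, "mult_vec"),
                                n_reps, level, seed = seed, lags = lags,
                                beta = beta)
  # analytic-noise replicates for the two-layer fit (per-cell sigma from the
  # cell's own clean curve)
  if ("twolayer" %in% estimators) {
    data_cells <- with_seed(seed + 1L, lapply(data_cells, function(cell) {
      sg <- analytic_acf_sigma(cell$clean, count_rate, t_int, beta)
      cell$noisy_raw <- t(vapply(seq_len(fit_reps), function(i)
        cell$clean$values + rnorm(length(lags), 0, sg$sigma),
        numeric(length(lags))))
      cell
    }))
  }

  rows <- list()
  for (est in estimators) {
    rec <- lapply(data_cells, .recover_cell, estimator = est, model = model,
                  prior = prior, sigma_analytic = NULL, lags = lags,
                  beta = beta)
    rec0 <- mean(rec[[1]])
    for (j in seq_along(cells_def)[-1]) {
      cd <- cells_def[[j]]
      layer_idx <- if (cd$layer == "brain") brain_layer else scalp_layer
      Db0 <- base_Db[layer_idx]
      Db <- Db0 * cd$multiplier
      s_rep <- sensitivity(rec[[j]], rec0, Db, Db0)
      bt <- bootstrap_mean(s_rep, seed = seed + j)
      # eps compares recovered relative flow against the true *brain* flow
      # change: the cell multiplier for brain cells, 1 for scalp confounds
      rDb_brain <- if (cd$layer == "brain") cd$multiplier else 1
      eps <- relative_error(mean(rec[[j]]) / rec0, rDb_brain)
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, layer = cd$layer, multiplier = cd$multiplier,
        true_Db = Db, mean_recovered = mean(rec[[j]]),
        baseline_recovered = rec0,
        S = mean(s_rep), S_boot = bt$mean, S_lo = bt$lower, S_hi = bt$upper,
        eps = eps, n_reps = length(rec[[j]]),
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(cells, cells$estimator), function(d) {
    data.frame(
      estimator = d$estimator[1],
      brain_S = mean(d$S[d$layer == "brain"]),
      scalp_S = mean(d$S[d$layer == "scalp"]),
      brain_abs_eps = mean(abs(d$eps[d$layer == "brain"])),
      scalp_abs_eps = mean(abs(d$eps[d$layer == "scalp"])),
      stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(cells = cells, summary = summ, n_reps = n_reps,
                 seed = seed, estimators = estimators),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' One-at-a-time stability sweep over head-model parameters
#'
#' Varies brain absorption, brain reduced scattering, scalp thickness and
#' skull thickness one at a time over five evenly spaced values (others at
#' the reference: mua = 0.015, musp = 1.1, Lscalp = 4 mm, Lskull = 7 mm),
#' rebuilds the Monte Carlo test curves per group, and reports recovered
#' CBFi error and rCBFi error (mean of the -50%/+50% brain-flow
#' perturbations) against the reference group for the chosen estimators.
#' Transport is reused across the brain-mua groups (absorption only enters
#' the tally weights).
#'
#' @param model a trained `dcs_regressor`
#' @param level a `sigma_profile` of SPAD-style noise
#' @param estimators subset of c("dl", "twolayer")
#' @param n_photons photons per transport run
#' @param n_reps noisy replicates per group
#' @param detector detector annulus, as in [run_layered_mc()]
#' @param seed integer seed
#' @param lags lag grid (seconds)
#' @param beta coherence factor
#' @param count_rate,t_int analytic-noise parameters for the two-layer fit
#' @param param_grids named list of the four sweeps (defaults as above)
#' @return data.frame of `stability_cell` rows: varied parameter, value,
#'   estimator, E_cbfi (%), E_rcbfi (%), reference flag
#' @export
run_stability_sweep <- function(model, level = default_sigma_profile(),
                                estimators = c("dl", "twolayer"),
                                n_photons = 1e6, n_reps = 50,
                                detector = list(rho = 35, half_width = 2.5),
                                seed = 1, lags = lag_grid(), beta = 0.5,
                                count_rate = 3300, t_int = 180,
                                param_grids = list(
                                  brain_mua = seq(0.005, 0.025, by = 0.005),
                                  brain_musp = seq(0.9, 1.3, by = 0.1),
                                  Lscalp = 2:6,
                                  Lskull = 5:9)) {
  ref <- list(brain_mua = 0.015, brain_musp = 1.1, Lscalp = 4, Lskull = 7)
  make_head <- function(p) {
    head_model(data.frame(
      name = c("scalp", "skull", "CSF", "brain"),
      thickness = c(p$Lscalp, p$Lskull, 2, Inf),
      mua = c(0.019, 0.014, 0.001, p$brain_mua),
      musp = c(0.726, 0.946, 0.002, p$brain_musp),
      Db = c(1e-6, 8e-8, 1e-8, 6e-6), stringsAsFactors = FALSE))
  }
  # one transport per distinct geometry/scattering; brain_mua reuses the
  # reference transport
  transports <- new.env(parent = emptyenv())
  get_ens <- function(p, run_seed) {
    key <- sprintf("musp%.3f_ls%g_lk%g", p$brain_musp, p$Lscalp, p$Lskull)
    if (is.null(transports[[key]]))
      transports[[key]] <- run_layered_mc(make_head(p), n_photons, detector,
                                          seed = run_seed)
    transports[[key]]
  }
  recover_group <- function(p, grp_seed) {
    ens <- get_ens(p, grp_seed)
    head_p <- make_head(p)
    mua <- head_p$layers$mua
    out <- list()
    for (est in estimators) {
      vals <- lapply(c(1, 0.5, 1.5), function(m) {
        Db <- head_p$layers$Db * c(1, 1, 1, m)
        clean <- g2_from_g1(g1_from_records(ens, Db, lags, mua = mua), beta)
        if (est == "dl") {
          noisy <- with_seed(grp_seed + round(100 * m), t(vapply(
            seq_len(n_reps), function(i) add_noise(clean, level)$values,
            numeric(length(lags)))))
          mean(predict_cbfi(model, noisy))
        } else {
          sg <- analytic_acf_sigma(clean, count_rate, t_int, beta)
          prior <- default_twolayer_prior(head_p, rho = detector$rho,
                                          beta = beta)
          prior$layer1$thickness <- p$Lscalp + p$Lskull
          reps <- with_seed(grp_seed + round(100 * m) + 1L, vapply(
            seq_len(n_reps), function(i) {
              y <- clean$values + rnorm(length(lags), 0, sg$sigma)
              fit_two_layer(acf_curve(lags, y, kind = "g2"), prior)$Db_brain
            }, numeric(1)))
          mean(reps)
        }
      })
      out[[est]] <- list(cbfi = vals[[1]],
                         rcbfi_lo = vals[[2]] / vals[[1]],
                         rcbfi_hi = vals[[3]] / vals[[1]])
    }
    out
  }
  ref_rec <- recover_group(ref, seed)
  rows <- list()
  for (param in names(param_grids)) {
    for (v in param_grids[[param]]) {
      p <- ref; p[[param]] <- v
      is_ref <- identical(unname(unlist(p)), unname(unlist(ref)))
      rec <- if (is_ref) ref_rec else
        recover_group(p, seed + length(rows) + 1L)
      for (est in estimators) {
        E_c <- stability_error(rec[[est]]$cbfi, ref_rec[[est]]$cbfi)
        E_r <- mean(c(
          stability_error(rec[[est]]$rcbfi_lo, ref_rec[[est]]$rcbfi_lo),
          stability_error(rec[[est]]$rcbfi_hi, ref_rec[[est]]$rcbfi_hi)))
        rows[[length(rows) + 1L]] <- data.frame(
          varied_param = param, value = v, estimator = est,
          E_cbfi = E_c, E_rcbfi = E_r, reference = is_ref,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
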