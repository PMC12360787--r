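#' Layered slab head model for photon Monte Carlo
#'
#' Default is the four-layer head (scalp, skull, CSF, brain) with
#' thicknesses 3, 7, 2 mm and a semi-infinite brain; per-layer absorption,
#' reduced scattering and Brownian diffusion coefficients at 785 nm; HG
#' anisotropy g = 0.89 and tissue refractive index 1.4 (index-matched
#' internal boundaries, Fresnel top surface against air).
#'
#' @param layers data.frame with columns `name`, `thickness` (mm, last Inf),
#'   `mua` (1/mm), `musp` (1/mm), `Db` (mm^2/s)
#' @param g_anisotropy HG anisotropy factor
#' @param n_tissue internal refractive index
#' @param wavelength wavelength (nm)
#' @param zmax,rmax slab depth and lateral bound (mm) terminating strays
#' @return an object of class `head_model`
#' @export
head_model <- function(layers = NULL, g_anisotropy = 0.89, n_tissue = 1.4,
                       wavelength = 785, zmax = 100, rmax = 150) {
  if (is.null(layers)) {
    layers <- data.frame(
      name = c("scalp", "skull", "CSF", "brain"),
      thickness = c(3, 7, 2, Inf),
      mua = c(0.019, 0.014, 0.001, 0.020),
      musp = c(0.726, 0.946, 0.002, 1.210),
      Db = c(1e-6, 8e-8, 1e-8, 6e-6),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(layers), nrow(layers) >= 1,
            is.infinite(layers$thickness[nrow(layers)]),
            all(layers$thickness > 0), all(layers$mua >= 0),
            all(layers$musp >= 0), all(layers$Db >= 0),
            g_anisotropy >= 0, g_anisotropy < 1)
  structure(list(layers = layers, g = g_anisotropy, n_tissue = n_tissue,
                 wavelength = wavelength, zmax = zmax, rmax = rmax,
                 k0 = 2 * pi * n_tissue / (wavelength * 1e-6)),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model %d layers (g=%.2f, n=%.2f)>\n",
              nrow(x$layers), x$g, x$n_tissue))
  print(x$layers)
  invisible(x)
}

#' Run the layered photon Monte Carlo
#'
#' Pencil beam normally incident at the origin; Henyey-Greenstein
#' scattering with the head model's anisotropy; scattering-only transport
#' (mus = musp/(1-g)) with absorption applied analytically at tally time.
#' Photons exiting the top surface with exit radius inside the detector
#' annulus are recorded with their per-layer pathlengths L and momentum
#' transfers Y = sum(1 - cos theta).
#'
#' @param head a `head_model`
#' @param n_photons photons to launch
#' @param detector list with `rho` (annulus center, mm) and `half_width`
#'   (mm); the capture band is [rho - half_width, rho + half_width]
#' @param seed integer RNG seed (single-threaded, bit-reproducible)
#' @param max_path kill threshold on total pathlength (mm)
#' @return an object of class `detected_ensemble` with matrices `L`, `Y`
#'   (n_detected x n_layers), `exit_radius`, counts and provenance
#' @export
run_layered_mc <- function(head, n_photons, detector = list(rho = 35, half_width = 0.5),
                           seed = 1, max_path = 3000) {
  stopifnot(inherits(head, "head_model"), n_photons >= 1)
  rho_min <- detector$rho - detector$half_width
  rho_max <- detector$rho + detector$half_width
  stopifnot(rho_min >= 0, rho_max <= head$rmax)
  mus <- ifelse(head$layers$musp > 0,
                head$layers$musp / (1 - head$g), 0)
  res <- mc_layered_cpp(pmin(head$layers$thickness, head$zmax), mus, head$g,
                        head$n_tissue, 1.0, rho_min, rho_max,
                        as.double(n_photons), max_path,
                        head$rmax, head$zmax, as.integer(seed))
  if (res$n_detected == 0)
    warning("no photons detected; ensemble is empty")
  colnames(res$L) <- colnames(res$Y) <- head$layers$name
  structure(list(L = res$L, Y = res$Y, exit_radius = res$exit_radius,
                 n_launched = res$n_launched, n_detected = res$n_detected,
                 detector = detector, seed = seed, head = head),
            class = "detected_ensemble")
}

#' @export
print.detected_ensemble <- function(x, ...) {
  cat(sprintf("<detected_ensemble %g/%g photons at rho=%g+/-%g mm>\n",
              x$n_detected, x$n_launched, x$detector$rho,
              x$detector$half_width))
  invisible(x)
}

#' Field autocorrelation from per-photon tallies
#'
#' g1(tau) = G1(tau)/G1(0) with
#' G1(tau) = (1/Np) sum_n exp(-2 k0^2 sum_i Y_ni Db_i tau)
#'                  exp(-sum_i mua_i L_ni).
#' Transport and dynamics are separated: the same ensemble serves any Db
#' (and any mua) without re-running the random walk.
#'
#' @param ensemble a `detected_ensemble`
#' @param Db per-layer Brownian coefficients (mm^2/s); default the head's
#' @param lags correlation lags (seconds)
#' @param mua per-layer absorption override (1/mm); default the head's
#' @return an `acf_curve` of kind "g1"
#' @export
g1_from_records <- function(ensemble, Db = NULL, lags = lag_grid(),
                            mua = NULL) {
  stopifnot(inherits(ensemble, "detected_ensemble"))
  if (ensemble$n_detected == 0) stop("empty ensemble")
  if (is.null(Db)) Db <- ensemble$head$layers$Db
  if (is.null(mua)) mua <- ensemble$head$layers$mua
  stopifnot(length(Db) == ncol(ensemble$L), length(mua) == ncol(ensemble$L))
  G <- g1_records_cpp(ensemble$L, ensemble$Y, mua, Db,
                      ensemble$head$k0, c(0, lags))
  acf_curve(lags, pmin(1, G[-1] / G[1]), kind = "g1")
}

#' Intensity autocorrelation from per-photon tallies
#'
#' @inheritParams g1_from_records
#' @param beta coherence factor
#' @return an `acf_curve` of kind "g2"
#' @export
g2_from_records <- function(ensemble, Db = NULL, lags = lag_grid(),
                            beta = 0.5, mua = NULL) {
  g2_from_g1(g1_from_records(ensemble, Db, lags, mua), beta)
}

#' Labeled Monte Carlo test curves under layer-flow perturbations
#'
#' For each perturbation (a vector of per-layer Db multipliers) the clean
#' four-layer g2 curve is synthesized from the shared ensemble and `n_reps`
#' noisy scaled replicates are drawn from the given noise level. The
#' transport is computed once; only the dynamics change between cells.
#'
#' @param ensemble a `detected_ensemble`
#' @param perturbations list of per-layer multiplier vectors
#' @param n_reps noisy replicates per perturbation
#' @param level a `sigma_profile`
#' @param seed integer seed
#' @param lags lag grid (seconds)
#' @param beta coherence factor
#' @return list of cells, each with `Db` (true per-layer values), `clean`
#'   (`acf_curve`), and `noisy` (n_reps x n_lags matrix of scaled values)
#' @export
mc_test_dataset <- function(ensemble, perturbations, n_reps, level,
                            seed = 1, lags = lag_grid(), beta = 0.5) {
  stopifnot(inherits(ensemble, "detected_ensemble"))
  base_Db <- ensemble$head$layers$Db
  with_seed(seed, lapply(perturbations, function(mult) {
    stopifnot(length(mult) == length(base_Db))
    Db <- base_Db * mult
    clean <- g2_from_records(ensemble, Db, lags, beta)
    noisy <- t(vapply(seq_len(n_reps),
                      function(i) add_noise(clean, level)$values,
                      numeric(length(lags))))
    list(Db = Db, multiplier = mult, clean = clean, noisy = noisy)
  }))
}
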