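# run an expression under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Min-max scaling of an autocorrelation curve to [1, 1.5]
#'
#' x = (X - min(X)) / (max(X) - min(X)) * 0.5 + 1. The transform is
#' idempotent and invariant to positive affine transforms of the input; the
#' output spans [1, 1.5] exactly.
#'
#' @param curve an `acf_curve` or numeric vector
#' @return same shape as the input; curves come back with kind "scaled"
#' @export
scale_acf <- function(curve) {
  v <- if (inherits(curve, "acf_curve")) curve$values else as.numeric(curve)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("degenerate input: constant curve cannot be scaled")
  out <- (v - rng[1]) / (rng[2] - rng[1]) * 0.5 + 1
  if (inherits(curve, "acf_curve"))
    return(acf_curve(curve$lags, out, kind = "scaled"))
  out
}

#' Stack of ACF frames on a shared lag grid
#'
#' @param frames n_frames x n_lags matrix of g2 values (one row per frame)
#' @param lags shared lag grid (seconds)
#' @param meta optional list (session id, frame period, ...)
#' @return an object of class `frame_stack`
#' @export
frame_stack <- function(frames, lags = lag_grid(), meta = list()) {
  frames <- as.matrix(frames)
  stopifnot(ncol(frames) == length(lags), all(diff(lags) > 0))
  structure(list(frames = frames, lags = as.numeric(lags), meta = meta),
            class = "frame_stack")
}

#' Per-lag noise standard deviation profile
#'
#' @param lags lag grid (seconds)
#' @param sigma per-lag standard deviations (>= 0, same length)
#' @param level_tag label such as "mean", "minus30", "plus30" or a session id
#' @return an object of class `sigma_profile`
#' @export
sigma_profile <- function(lags, sigma, level_tag = "session") {
  stopifnot(length(lags) == length(sigma), all(sigma >= 0))
  structure(list(lags = as.numeric(lags), sigma = as.numeric(sigma),
                 level_tag = level_tag), class = "sigma_profile")
}

#' Estimate the per-lag noise profile from a stack of baseline frames
#'
#' Each frame is min-max scaled to [1, 1.5], fitted with a single-exponential
#' decay, and the residual retained; sigma(tau) is the standard deviation of
#' the residuals across frames at each lag. Because a 3-parameter fit
#' absorbs part of the noise, the raw residual spread underestimates sigma
#' by sqrt(1 - h_j) with h_j the fit leverage at lag j; the estimate is
#' corrected by the average linearized leverage across frames (standard
#' degrees-of-freedom correction). Frames whose fit fails are dropped with
#' a warning.
#'
#' Note the min-max scaling pins the frame's maximum (in practice the first
#' lag of a decaying curve) to 1.5 and its minimum to 1.0 exactly, so the
#' estimated sigma at those pinned lags is intrinsically suppressed — a
#' property of the scaling step itself, visible in measured SPAD profiles,
#' not a bias this function can remove.
#'
#' @param stack a `frame_stack` with >= 2 frames
#' @return a `sigma_profile`
#' @export
estimate_sigma <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- nrow(stack$frames)
  if (n < 2L) stop("need at least 2 frames to estimate sigma")
  nl <- ncol(stack$frames)
  res <- matrix(NA_real_, n, nl)
  hsum <- numeric(nl)
  ok <- logical(n)
  for (i in seq_len(n)) {
    r <- tryCatch({
      sc <- scale_acf(stack$frames[i, ])
      fit_single_exponential(sc, lags = stack$lags)
    }, error = function(e) NULL)
    if (!is.null(r)) {
      res[i, ] <- r$residuals
      ok[i] <- TRUE
      e <- exp(-r$c * stack$lags)
      J <- cbind(1, e, -r$b * stack$lags * e)
      h <- rowSums((J %*% solve(crossprod(J))) * J)
      hsum <- hsum + pmin(h, 0.99)
    }
  }
  if (!any(ok)) stop("all frames failed the single-exponential fit")
  if (any(!ok))
    warning(sprintf("%d/%d frames failed the fit and were dropped",
                    sum(!ok), n))
  hbar <- hsum / sum(ok)
  sigma <- apply(res[ok, , drop = FALSE], 2, sd) / sqrt(1 - hbar)
  sigma_profile(stack$lags, sigma,
                level_tag = stack$meta$session %||% "session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the three training noise levels from session profiles
#'
#' Averages the supplied per-session profiles elementwise and scales the
#' mean by +/-30% to bracket inter-session variability, yielding the
#' `minus30`, `mean` and `plus30` levels used for training-set synthesis.
#'
#' @param profiles a `sigma_profile` or list of them on one lag grid
#' @return named list of three `sigma_profile`s
#' @export
make_noise_levels <- function(profiles) {
  if (inherits(profiles, "sigma_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "sigma_profile")))
  lags <- profiles[[1]]$lags
  m <- rowMeans(vapply(profiles, function(p) p$sigma, numeric(length(lags))))
  list(minus30 = sigma_profile(lags, 0.7 * m, "minus30"),
       mean = sigma_profile(lags, m, "mean"),
       plus30 = sigma_profile(lags, 1.3 * m, "plus30"))
}

#' Add per-lag Gaussian noise to a clean curve, SPAD-style
#'
#' The clean curve is min-max scaled to [1, 1.5], independent zero-mean
#' Gaussian noise with the profile's per-lag sigma is added, and the result
#' is rescaled with the same transform (so every sample presented to the
#' regressor spans [1, 1.5] exactly).
#'
#' @param clean an `acf_curve` on the profile's lag grid
#' @param level a `sigma_profile`
#' @param seed optional integer seed for reproducibility
#' @return an `acf_curve` of kind "scaled"
#' @export
add_noise <- function(clean, level, seed = NULL) {
  stopifnot(inherits(clean, "acf_curve"), inherits(level, "sigma_profile"))
  if (length(clean$lags) != length(level$lags) ||
      max(abs(clean$lags - level$lags)) > 1e-12)
    stop("curve and noise profile must share one lag grid")
  sc <- scale_acf(clean)
  noisy <- with_seed(seed, sc$values + rnorm(length(sc$values), 0, level$sigma))
  scale_acf(acf_curve(clean$lags, noisy, kind = "g2"))
}

#' Analytic shot-noise model of the correlation standard deviation
#'
#' Per-lag standard deviation of a linear-tau correlator estimate of g2,
#' after Koppel's variance formula: with bin width t (the lag step), decay
#' rate Gamma of g1 (estimated from the curve by single-exponential fit,
#' Gamma = c/2), mean photons per bin n = count_rate * t and lag index
#' m = tau/t,
#' sigma(tau) = sqrt(t/t_int) * [ beta^2 ((1+e^{-2G t})(1+e^{-2G tau})
#'   + 2m(1-e^{-2G t}) e^{-2G tau}) / (1-e^{-2G t})
#'   + 2 n^{-1} beta (1+e^{-2G tau}) + n^{-2} (1+beta e^{-G tau}) ]^{1/2}.
#' sigma scales as 1/sqrt(t_int) and decreases with count rate.
#'
#' @param g2 an `acf_curve` of kind "g2" (clean model curve)
#' @param count_rate detected photon count rate (Hz)
#' @param t_int integration time (seconds)
#' @param beta coherence factor
#' @return a `sigma_profile` on the curve's lag grid
#' @export
analytic_acf_sigma <- function(g2, count_rate, t_int, beta = 0.5) {
  stopifnot(inherits(g2, "acf_curve"), count_rate > 0, t_int > 0)
  tau <- g2$lags
  t_bin <- tau[1]                     # linear-tau sampling: bin = first lag
  gamma <- fit_single_exponential(g2)$c / 2
  n <- count_rate * t_bin
  m <- tau / t_bin
  e2t <- exp(-2 * gamma * t_bin)
  e2tau <- exp(-2 * gamma * tau)
  etau <- exp(-gamma * tau)
  v <- beta^2 * ((1 + e2t) * (1 + e2tau) + 2 * m * (1 - e2t) * e2tau) /
         (1 - e2t) +
       2 * n^(-1) * beta * (1 + e2tau) + n^(-2) * (1 + beta * etau)
  sigma_profile(tau, sqrt(t_bin / t_int) * sqrt(v), level_tag = "analytic")
}

#' Default SPAD-like per-lag noise profile
#'
#' Stand-in (synthetic) for a subject-specific baseline noise estimate:
#' sigma(tau) = 0.02 * (0.5 + exp(-tau / 15 microseconds)), about 0.03 at
#' the earliest lags decaying to about 0.013 at the last. The magnitude is
#' consistent with the analytic shot-noise level at a few kHz count rate on
#' curves scaled to [1, 1.5].
#'
#' @param lags lag grid (seconds)
#' @return a `sigma_profile`
#' @export
default_sigma_profile <- function(lags = lag_grid()) {
  sigma_profile(lags, 0.02 * (0.5 + exp(-lags / 15e-6)), level_tag = "mean")
}

#' Synthesize baseline ACF frame stacks (SPAD-session emulator)
#'
#' Emulates a resting-state recording session: every frame is the same clean
#' curve (scaled to [1, 1.5]) plus zero-mean per-lag Gaussian noise from the
#' supplied profile. Used to exercise the noise-estimation loop without any
#' measurement; frames are *not* rescaled after noise so the injected sigma
#' is recoverable exactly.
#'
#' @param clean an `acf_curve` (clean baseline shape)
#' @param n_frames number of frames in the session
#' @param level a `sigma_profile` of injected noise
#' @param seed integer seed
#' @param session session id stored in the stack meta
#' @return a `frame_stack`
#' @export
simulate_baseline_frames <- function(clean, n_frames, level, seed = NULL,
                                     session = "synthetic") {
  stopifnot(inherits(clean, "acf_curve"), n_frames >= 1,
            inherits(level, "sigma_profile"))
  sc <- scale_acf(clean)
  nl <- length(sc$values)
  noise <- with_seed(seed,
    matrix(rnorm(n_frames * nl, 0, rep(level$sigma, each = n_frames)),
           n_frames, nl))
  frame_stack(sweep(noise, 2, sc$values, `+`), lags = clean$lags,
              meta = list(session = session, seed = seed))
}
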