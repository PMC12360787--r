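#' Optical and dynamic properties of a single tissue layer
#'
#' Bundles the per-layer quantities entering the correlation diffusion
#' equation: absorption, reduced scattering, the effective Brownian
#' diffusion coefficient of the moving scatterers, the layer thickness and
#' the moving-scatterer fraction.
#'
#' @param mua absorption coefficient (1/mm); may be >= 0 for CSF-like layers
#' @param musp reduced scattering coefficient (1/mm), > 0
#' @param Db effective Brownian diffusion coefficient (mm^2/s), >= 0
#' @param thickness layer thickness (mm); `Inf` for a semi-infinite layer
#' @param alpha moving-scatterer fraction (dimensionless, default 1)
#' @return an object of class `layer_optics`
#' @export
layer_optics <- function(mua, musp, Db, thickness = Inf, alpha = 1) {
  stopifnot(is.numeric(mua), length(mua) == 1L, mua >= 0,
            is.numeric(musp), length(musp) == 1L, musp > 0,
            is.numeric(Db), length(Db) == 1L, Db >= 0,
            is.numeric(thickness), length(thickness) == 1L, thickness > 0,
            alpha > 0, alpha <= 1)
  structure(list(mua = mua, musp = musp, Db = Db,
                 thickness = thickness, alpha = alpha),
            class = "layer_optics")
}

#' Effective reflection coefficient at a refractive-index-mismatched surface
#'
#' Computes Reff from the internal refractive index by angular integration
#' of the unpolarized Fresnel reflectance over the fluence and flux moments
#' (Reff = (R_phi + R_j) / (2 - R_phi + R_j)). For n0 = 1.4 this gives
#' approximately 0.493.
#'
#' @param n0 internal refractive index (external medium assumed n = 1)
#' @return scalar Reff in [0, 1)
#' @export
effective_reflection <- function(n0) {
  stopifnot(n0 >= 1)
  if (n0 == 1) return(0)
  rf <- function(theta) {
    ci <- cos(theta)
    st2 <- n0^2 * sin(theta)^2
    r <- ifelse(st2 >= 1, 1, {
      ct <- sqrt(pmax(0, 1 - st2))
      rs <- (n0 * ci - ct) / (n0 * ci + ct)
      rp <- (n0 * ct - ci) / (n0 * ct + ci)
      0.5 * (rs^2 + rp^2)
    })
    r
  }
  rphi <- integrate(function(th) 2 * sin(th) * cos(th) * rf(th), 0, pi / 2,
                    rel.tol = 1e-10)$value
  rj <- integrate(function(th) 3 * sin(th) * cos(th)^2 * rf(th), 0, pi / 2,
                  rel.tol = 1e-10)$value
  (rphi + rj) / (2 - rphi + rj)
}

#' Two-layer turbid medium for the correlation diffusion solution
#'
#' Assembles the extracerebral (finite) and brain (semi-infinite) layers
#' together with the measurement geometry and derives the boundary-condition
#' constants of the diffusion solution: wavenumber k0 = 2*pi*n0/lambda,
#' isotropic source depth z0 = 1/(mua1 + musp1), photon diffusion
#' coefficients Dj = 1/(3*musp_j) and extrapolated boundary distance
#' zb = 2*D1*(1+Reff)/(1-Reff).
#'
#' @param layer1 `layer_optics` for the extracerebral layer (finite thickness)
#' @param layer2 `layer_optics` for the brain (thickness `Inf`)
#' @param rho source-detector separation (mm)
#' @param wavelength wavelength (nm)
#' @param n0 tissue refractive index
#' @param beta Siegert coherence factor, in (0, 1]
#' @param Reff effective reflection coefficient; computed from `n0` if `NULL`
#' @return an object of class `two_layer_medium`
#' @export
two_layer_medium <- function(layer1, layer2, rho = 35, wavelength = 785,
                             n0 = 1.4, beta = 0.5, Reff = NULL) {
  stopifnot(inherits(layer1, "layer_optics"), inherits(layer2, "layer_optics"),
            is.finite(layer1$thickness), rho > 0, wavelength > 0,
            beta > 0, beta <= 1)
  if (is.null(Reff)) Reff <- effective_reflection(n0)
  k0 <- 2 * pi * n0 / (wavelength * 1e-6)   # nm -> mm
  D1 <- 1 / (3 * layer1$musp)
  D2 <- 1 / (3 * layer2$musp)
  z0 <- 1 / (layer1$mua + layer1$musp)
  zb <- 2 * D1 * (1 + Reff) / (1 - Reff)
  structure(list(layer1 = layer1, layer2 = layer2, rho = rho,
                 wavelength = wavelength, n0 = n0, beta = beta, Reff = Reff,
                 k0 = k0, D1 = D1, D2 = D2, z0 = z0, zb = zb),
            class = "two_layer_medium")
}

#' Linearly spaced correlation lag grid
#'
#' @param n number of lags (>= 2)
#' @param step lag increment (seconds), > 0
#' @return numeric vector `c(step, 2*step, ..., n*step)`
#' @examples
#' tail(lag_grid(31, 1.28e-6), 1)  # 39.68 microseconds
#' @export
lag_grid <- function(n = 31, step = 1.28e-6) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be a positive scalar")
  stopifnot(n >= 2)
  seq_len(n) * step
}

#' Autocorrelation curve container
#'
#' @param lags strictly increasing correlation lags (seconds)
#' @param values dimensionless samples of the autocorrelation
#' @param kind one of "g1", "g2", "scaled"
#' @return an object of class `acf_curve`
#' @export
acf_curve <- function(lags, values, kind = c("g2", "g1", "scaled")) {
  kind <- match.arg(kind)
  stopifnot(length(lags) == length(values), all(diff(lags) > 0),
            all(is.finite(values)))
  eps <- 1e-6
  if (kind == "g1" && (any(values < -eps) || any(values > 1 + eps)))
    stop("g1 values must lie in [0, 1]")
  structure(list(lags = as.numeric(lags), values = as.numeric(values),
                 kind = kind), class = "acf_curve")
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("<acf_curve kind=%s, %d lags: %.3g..%.3g s, values %.4f..%.4f>\n",
              x$kind, length(x$lags), min(x$lags), max(x$lags),
              min(x$values), max(x$values)))
  invisible(x)
}

# approximate positive zeros of J0 (adequate for panel splitting)
bessel_j0_zeros <- function(k) {
  b <- (k - 0.25) * pi
  b + 1 / (8 * b) - 31 / (384 * b^3)
}

# Gauss-Legendre panels for the inverse Hankel transform, split at the zeros
# of J0(s*rho) so each panel holds at most a half-oscillation. Returns nodes
# and combined weights w_i = gl_w * s_i * J0(s_i*rho) / (2*pi), i.e. the
# integral (1/2pi) * int G~(s) s J0(s rho) ds becomes sum(w * G~(s)).
hankel_context <- function(rho, s_max = 25, order = 10) {
  ref <- pracma::gaussLegendre(order, -1, 1)
  zeros <- bessel_j0_zeros(seq_len(5000)) / rho
  brk <- c(0, zeros[zeros < s_max], s_max)
  # also cap the panel width so small-rho cases still resolve the kernel
  brk <- sort(unique(c(brk, seq(0, s_max, by = 0.5))))
  s <- w <- numeric(0)
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    if (b - a < 1e-12) next
    si <- 0.5 * (b - a) * ref$x + 0.5 * (a + b)
    wi <- 0.5 * (b - a) * ref$w
    s <- c(s, si); w <- c(w, wi)
  }
  list(s = s, w = w * s * besselJ(s * rho, 0) / (2 * pi),
       rho = rho, s_max = s_max, order = order)
}

# consistent-unit alpha_j^2 used throughout (see vignette): the tau-dependent
# dynamic absorption is 2*alpha*musp*k0^2*Db*tau, from (1/3)k0^2 musp <dr^2>
# with <dr^2> = 6 Db tau.
.kernel_consts <- function(medium) {
  list(mua1 = medium$layer1$mua, musp1 = medium$layer1$musp,
       Db1 = medium$layer1$Db, af1 = medium$layer1$alpha,
       mua2 = medium$layer2$mua, musp2 = medium$layer2$musp,
       Db2 = medium$layer2$Db, af2 = medium$layer2$alpha,
       l = medium$layer1$thickness, k0 = medium$k0,
       z0 = medium$z0, zb = medium$zb)
}

#' Fourier-domain two-layer correlation kernel at the surface
#'
#' Evaluates the two-layer correlation-diffusion kernel at spatial frequency
#' `s` and lag `tau` for the given medium, in the overflow-safe form used by
#' the inverse Hankel transform (every exponential argument non-positive).
#'
#' @param s spatial frequency (1/mm), vectorized, >= 0
#' @param tau correlation lag (seconds), scalar >= 0
#' @param medium a `two_layer_medium`
#' @return kernel values, same length as `s`
#' @export
g1_tilde_twolayer <- function(s, tau, medium) {
  stopifnot(all(s >= 0), length(tau) == 1L, tau >= 0)
  p <- .kernel_consts(medium)
  D1 <- 1 / (3 * p$musp1); D2 <- 1 / (3 * p$musp2)
  K1sq <- (p$mua1 + 2 * p$af1 * p$musp1 * p$k0^2 * p$Db1 * tau) / D1
  K2sq <- (p$mua2 + 2 * p$af2 * p$musp2 * p$k0^2 * p$Db2 * tau) / D2
  a1 <- sqrt(s^2 + K1sq); a2 <- sqrt(s^2 + K2sq)
  d1a1 <- D1 * a1; d2a2 <- D2 * a2
  e2l <- exp(-2 * a1 * p$l); e2lb <- exp(-2 * a1 * (p$l + p$zb))
  den <- d1a1 * (1 + e2lb) + d2a2 * (1 - e2lb)
  R <- (d1a1 * (1 + e2l) + d2a2 * (1 - e2l)) / den
  out <- (exp(-a1 * p$z0) - exp(-a1 * (p$z0 + 2 * p$zb)) * R +
          (d1a1 - d2a2) * (1 - exp(-2 * a1 * p$zb)) *
            exp(-a1 * (2 * p$l - p$z0)) / den) / (2 * d1a1)
  if (any(!is.finite(out))) stop("two-layer kernel evaluated to NaN/Inf")
  out
}

# unnormalized G1 at given lags: closed-form semi-infinite part of layer 1
# (Sommerfeld identity) plus the numerically integrated layer-mismatch term
.G1_twolayer <- function(medium, tau, ctx) {
  p <- .kernel_consts(medium)
  D1 <- 1 / (3 * p$musp1)
  Ksq <- 3 * p$musp1 * p$mua1 +
    6 * p$af1 * p$musp1^2 * p$k0^2 * p$Db1 * tau
  r1 <- sqrt(ctx$rho^2 + p$z0^2)
  rb <- sqrt(ctx$rho^2 + (p$z0 + 2 * p$zb)^2)
  Gsemi <- (exp(-sqrt(Ksq) * r1) / r1 - exp(-sqrt(Ksq) * rb) / rb) /
    (4 * pi * D1)
  Gsemi + g1_hankel_cpp(ctx$s, ctx$w, tau,
                        p$mua1, p$musp1, p$Db1, p$af1,
                        p$mua2, p$musp2, p$Db2, p$af2,
                        p$l, p$k0, p$z0, p$zb)
}

#' Normalized field autocorrelation of the two-layer medium
#'
#' Computes G1(rho, z = 0, tau) by inverse Hankel transform of the
#' Fourier-domain two-layer kernel (Gauss-Legendre panels split at the zeros
#' of J0(s*rho)) and returns g1(tau) = G1(tau)/G1(0). The quadrature is
#' verified by re-evaluating at doubled panel order; if the two estimates
#' disagree beyond `rel_tol` the order is raised once more, and failure to
#' converge raises an error carrying the achieved error estimate.
#'
#' @param medium a `two_layer_medium`
#' @param tau correlation lags (seconds), vectorized, >= 0
#' @param rel_tol relative agreement required between quadrature refinements
#' @param s_max upper integration limit (1/mm)
#' @return numeric vector of g1 values in [0, 1]
#' @export
g1_twolayer <- function(medium, tau, rel_tol = 1e-8, s_max = 25) {
  stopifnot(all(tau >= 0))
  tt <- c(0, tau)
  ords <- c(10, 20, 40)
  prev <- NULL
  for (k in seq_along(ords)) {
    ctx <- .hankel_ctx_cached(medium$rho, s_max, ords[k])
    G <- .G1_twolayer(medium, tt, ctx)
    g1 <- G / G[1]
    if (!is.null(prev)) {
      # g1 is normalized to [0, 1]; agreement is judged on the larger of the
      # relative and absolute scale so machine-small tails cannot dominate
      err <- max(abs(g1 - prev) / pmax(abs(g1), 1e-3))
      if (err <= rel_tol) return(g1[-1])
    }
    prev <- g1
  }
  stop(sprintf("Hankel quadrature did not converge: achieved %.3g > rel_tol %.3g",
               err, rel_tol))
}

# context cache (keyed by rho/s_max/order) so repeated evaluations at one
# geometry skip the Bessel setup
.ctx_cache <- new.env(parent = emptyenv())
.hankel_ctx_cached <- function(rho, s_max, order) {
  key <- sprintf("%.10g_%.10g_%d", rho, s_max, order)
  if (is.null(.ctx_cache[[key]]))
    .ctx_cache[[key]] <- hankel_context(rho, s_max, order)
  .ctx_cache[[key]]
}

#' Semi-infinite homogeneous closed-form field autocorrelation
#'
#' Verification oracle: the standard image-source solution
#' g1(tau) = [exp(-K(tau) r1)/r1 - exp(-K(tau) rb)/rb] /
#'           [exp(-K(0) r1)/r1 - exp(-K(0) rb)/rb]
#' with K^2(tau) = 3*musp*mua + 6*alpha*musp^2*k0^2*Db*tau,
#' r1 = sqrt(rho^2 + z0^2), rb = sqrt(rho^2 + (z0 + 2 zb)^2).
#'
#' @param optics a `layer_optics`
#' @param rho source-detector separation (mm)
#' @param tau correlation lags (seconds), vectorized
#' @param wavelength wavelength (nm)
#' @param n0 refractive index
#' @param Reff effective reflection coefficient; from `n0` if `NULL`
#' @return numeric vector of g1 values
#' @export
g1_semiinfinite <- function(optics, rho, tau, wavelength = 785, n0 = 1.4,
                            Reff = NULL) {
  stopifnot(inherits(optics, "layer_optics"), all(tau >= 0))
  if (is.null(Reff)) Reff <- effective_reflection(n0)
  k0 <- 2 * pi * n0 / (wavelength * 1e-6)
  D <- 1 / (3 * optics$musp)
  z0 <- 1 / (optics$mua + optics$musp)
  zb <- 2 * D * (1 + Reff) / (1 - Reff)
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  Kt <- sqrt(3 * optics$musp * optics$mua +
             6 * optics$alpha * optics$musp^2 * k0^2 * optics$Db * tau)
  K0 <- sqrt(3 * optics$musp * optics$mua)
  G <- exp(-Kt * r1) / r1 - exp(-Kt * rb) / rb
  G0 <- exp(-K0 * r1) / r1 - exp(-K0 * rb) / rb
  G / G0
}

#' Siegert relation: intensity from field autocorrelation
#'
#' g2 = 1 + beta * |g1|^2. Accepts a numeric vector or an `acf_curve` of
#' kind "g1" (returned as kind "g2").
#'
#' @param g1 field autocorrelation values or an `acf_curve`
#' @param beta coherence factor in (0, 1]
#' @return same shape as the input
#' @export
g2_from_g1 <- function(g1, beta) {
  stopifnot(beta > 0, beta <= 1)
  if (inherits(g1, "acf_curve"))
    return(acf_curve(g1$lags, 1 + beta * abs(g1$values)^2, kind = "g2"))
  1 + beta * abs(g1)^2
}

#' Two-layer model intensity autocorrelation curve
#'
#' Convenience wrapper: `g1_twolayer` followed by the Siegert relation at
#' the medium's coherence factor.
#'
#' @param medium a `two_layer_medium`
#' @param lags correlation lags (seconds); default the 31-lag SPAD grid
#' @param ... passed to [g1_twolayer()]
#' @return an `acf_curve` of kind "g2"
#' @export
g2_curve <- function(medium, lags = lag_grid(), ...) {
  g1 <- g1_twolayer(medium, lags, ...)
  acf_curve(lags, 1 + medium$beta * g1^2, kind = "g2")
}
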