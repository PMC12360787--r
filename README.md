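# dcs2l — two-layer diffuse correlation spectroscopy modelling and recurrent blood-flow regression

`dcs2l` is an R package for researchers in diffuse optics and cerebral
hemodynamics who need a complete, reproducible bench for two-layer diffuse
correlation spectroscopy (DCS) analysis at large source–detector
separation. DCS measures microvascular blood flow from the intensity
autocorrelation g2(τ) of multiply scattered coherent light; through the
Siegert relation g2 = 1 + β|g1|², the field autocorrelation g1 decays with
the blood flow index (BFi = αDb, mm²/s) of the probed tissue. On the adult
head, scalp and skull confound the brain signal, so the package models the
head as a finite extracerebral layer over a semi-infinite brain and builds
everything needed to train and evaluate estimators of cerebral blood flow
index (CBFi):

- **Forward models** — the two-layer correlation-diffusion solution
  g̃1(s, τ) (inverse Hankel transform with α_j² = s² + (μa,j +
  2α μs,j′ k0² Db,j τ)/D_j, D_j = 1/(3 μs,j′)), plus the semi-infinite
  closed form used as an exact oracle.
- **Fitting** — single-exponential g2 = a + b·e^(−cτ) with decorrelation
  speed c/2, and full two-layer inversion for (Db_extra, Db_brain).
- **Noise** — min–max curve scaling to [1, 1.5], per-lag σ(τ) estimation
  from baseline frame stacks, ±30% level construction, Gaussian noise
  injection, and the analytic (Koppel-type) correlator noise model.
- **Data generation** — the 5×5×8×100×20 = 400,000-medium parameter grid
  (Db_brain 5×10⁻⁷…5×10⁻⁵ mm²/s), noisy training corpora with
  CBFi×10⁶ labels, and pulsatile brain / ramping scalp flow scenarios.
- **Monte Carlo head model** — layered-slab photon transport (scalp,
  skull, CSF, brain; Henyey–Greenstein g = 0.89) with per-layer
  pathlength and momentum-transfer tallies, so one ensemble yields g1 for
  any layer dynamics: G1(τ) = (1/Np) Σ exp(−2k0² Σᵢ Yᵢ Dbᵢ τ)·exp(−Σᵢ μaᵢ Lᵢ).
- **Regressor** — a 2×128-unit LSTM (198,273 trainable parameters) mapping
  scaled 31-lag curves (1.28–39.68 µs) to CBFi, written in RcppArmadillo
  with Adam, dropout and weight decay.
- **Evaluation** — sensitivity S = (ΔCBFi/CBFi0)/(ΔDb/Db0)×100, relative
  flow error ε, stability error E, bootstrap uncertainty, and the
  orchestrated comparison of the three estimators.

## Worked example

```r
library(dcs2l)

# a two-layer head: extracerebral layer over brain, 35 mm separation
med <- two_layer_medium(
  layer1 = layer_optics(mua = 0.019, musp = 0.86, Db = 1.05e-6, thickness = 11),
  layer2 = layer_optics(mua = 0.015, musp = 1.10, Db = 6e-6),
  rho = 35, beta = 0.5)

g2 <- g2_curve(med)                      # clean 31-lag intensity ACF
round(g2$values[c(1, 5, 15, 31)], 4)
#> [1] 1.4115 1.2145 1.0623 1.0129

# inject SPAD-style noise and invert with the two-layer model
noisy <- add_noise(g2, default_sigma_profile(), seed = 1)
fit <- fit_two_layer(g2, med)
fit
#> <twolayer_fit Db_extra=1.05e-06 Db_brain=6e-06 mm^2/s, obj=7.8e-29, converged (6 it)>
```

The fitted `Db_brain = 6e-06 mm²/s` recovers the generating brain flow
index exactly on the noiseless curve (the "inverse crime" sanity bound is
< 0.1% relative); `obj` is the final sum of squared residuals over the 31
lags. A single-exponential fit of the same curve gives the decorrelation
speed (`decorrelation_speed(fit_single_exponential(g2))`, here
6.13e4 s⁻¹), the fast estimator whose relative changes track relative flow.

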