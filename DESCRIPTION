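Package: dcs2l
Title: Two-Layer Diffuse Correlation Spectroscopy Modelling and Recurrent
    Blood-Flow Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling, noise synthesis and inversion tools for
    diffuse correlation spectroscopy (DCS) of the human head. Implements
    the two-layer correlation-diffusion analytical solution (inverse
    Hankel transform of the Fourier-domain kernel), the semi-infinite
    closed form, single-exponential and two-layer curve fitting of
    intensity autocorrelation (g2) data, SPAD-style per-lag Gaussian noise
    estimation and injection, a layered photon Monte Carlo with per-layer
    pathlength and momentum-transfer tallies, an LSTM sequence regressor
    mapping 31-lag g2 curves to cerebral blood flow index (CBFi), and an
    evaluation harness for sensitivity, relative-error and stability
    analyses of the competing estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
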