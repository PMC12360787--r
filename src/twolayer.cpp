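#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Fourier-domain two-layer correlation-diffusion kernel, surface (z = 0),
// split as  kernel = semi-infinite(layer 1) + delta(layer mismatch):
//
//   kernel_semi = (e^{-a1 z0} - e^{-a1 (z0+2 zb)}) / (2 D1 a1)
//   delta = (D1 a1 - D2 a2)(1-e^{-2 a1 zb})
//           (e^{-a1 (2l - z0)} - e^{-a1 (2l + z0 + 2 zb)}) / (2 D1 a1 den)
//   den   = D1 a1 (1+e^{-2 a1 (l+zb)}) + D2 a2 (1-e^{-2 a1 (l+zb)})
//
// with alpha_j^2 = s^2 + (mua_j + 2*afrac_j*musp_j*k0^2*Db_j*tau)/D_j and
// D_j = 1/(3*musp_j) [mm]. The semi-infinite part has the closed-form
// inverse Hankel transform (image-source solution), so only the mismatch
// term delta -- O(e^{-2 a1 l}), free of large oscillatory cancellation --
// is integrated numerically. All exponential arguments are non-positive
// (requires 2*l > z0, always true for tissue layers). This routine returns
// the delta integral; the caller adds the closed-form part.

// [[Rcpp::export]]
NumericVector g1_hankel_cpp(NumericVector s, NumericVector w,
                            NumericVector tau,
                            double mua1, double musp1, double Db1, double af1,
                            double mua2, double musp2, double Db2, double af2,
                            double l, double k0, double z0, double zb) {
  const int ns = s.size(), nt = tau.size();
  const double D1 = 1.0 / (3.0 * musp1);
  const double D2 = 1.0 / (3.0 * musp2);
  const double k0sq = k0 * k0;
  NumericVector out(nt);
  for (int j = 0; j < nt; ++j) {
    const double K1sq = (mua1 + 2.0 * af1 * musp1 * k0sq * Db1 * tau[j]) / D1;
    const double K2sq = (mua2 + 2.0 * af2 * musp2 * k0sq * Db2 * tau[j]) / D2;
    double acc = 0.0;
    for (int i = 0; i < ns; ++i) {
      const double ssq = s[i] * s[i];
      const double a1 = std::sqrt(ssq + K1sq);
      const double a2 = std::sqrt(ssq + K2sq);
      const double d1a1 = D1 * a1, d2a2 = D2 * a2;
      const double e2lb = std::exp(-2.0 * a1 * (l + zb));
      const double den = d1a1 * (1.0 + e2lb) + d2a2 * (1.0 - e2lb);
      const double delta = (d1a1 - d2a2) *
        (1.0 - std::exp(-2.0 * a1 * zb)) *
        (std::exp(-a1 * (2.0 * l - z0)) -
         std::exp(-a1 * (2.0 * l + z0 + 2.0 * zb))) / (2.0 * d1a1 * den);
      acc += w[i] * delta;
    }
    out[j] = acc;
  }
  return out;
}
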