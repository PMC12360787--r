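#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// Layered-slab photon Monte Carlo with per-layer pathlength (L) and
// momentum-transfer (Y = sum of 1-cos(theta)) tallies.
//
// Transport is scattering-only: absorption is applied analytically at tally
// time via exp(-sum mua_i L_i), so mua never enters the random walk and the
// same ensemble serves any set of layer dynamics or absorptions.
//
// Geometry: layers stacked in z >= 0, pencil beam incident at the origin
// along +z. The top surface has a refractive-index step n_in -> n_out with
// Fresnel reflection; internal boundaries are index-matched. Photons exiting
// the top surface with exit radius in [rho_min, rho_max] are recorded.

// xoshiro256++ (public-domain algorithm), seeded via splitmix64: much
// faster than mt19937_64 in this tight loop and of ample quality for
// photon transport
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]
  inline double u01p() { return ((next() >> 11) + 1) * 0x1.0p-53; }
};

static inline double fresnel_R(double n_in, double n_out, double cos_i) {
  // unpolarized Fresnel reflectance for incidence cosine cos_i (>0)
  const double nr = n_in / n_out;
  const double sin_i2 = 1.0 - cos_i * cos_i;
  const double sin_t2 = nr * nr * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  const double cos_t = std::sqrt(1.0 - sin_t2);
  const double rs = (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t);
  const double rp = (n_in * cos_t - n_out * cos_i) / (n_in * cos_t + n_out * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List mc_layered_cpp(NumericVector thickness, NumericVector mus, double g,
                    double n_in, double n_out,
                    double rho_min, double rho_max,
                    double n_photons, double max_path,
                    double rmax, double zmax, int seed) {
  const int nl = thickness.size();
  std::vector<double> zhi(nl);  // lower boundary depth of each layer
  double zc = 0.0;
  for (int i = 0; i < nl; ++i) {
    zc += thickness[i];
    zhi[i] = (i == nl - 1) ? zmax : std::min(zc, zmax);
  }
  Xoshiro rng(static_cast<uint64_t>(seed));

  std::vector<double> Lrec, Yrec, Rrec;
  const long long np = static_cast<long long>(n_photons);
  std::vector<double> L(nl), Y(nl);
  long long ndet = 0;

  for (long long n = 0; n < np; ++n) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double total = 0.0;
    std::fill(L.begin(), L.end(), 0.0);
    std::fill(Y.begin(), Y.end(), 0.0);
    int lay = 0;
    bool alive = true, detected = false;

    double remaining = -std::log(rng.u01p());  // dimensionless step

    while (alive) {
      const double zlo = (lay == 0) ? 0.0 : zhi[lay - 1];
      const double mus_l = mus[lay];
      // distance to layer boundary along uz
      double db = std::numeric_limits<double>::infinity();
      if (uz > 0.0)      db = (zhi[lay] - z) / uz;
      else if (uz < 0.0) db = (zlo - z) / uz;
      const double ds = (mus_l > 0.0) ? remaining / mus_l
                                      : std::numeric_limits<double>::infinity();
      if (ds < db) {
        // scatter inside the layer
        x += ux * ds; y += uy * ds; z += uz * ds;
        L[lay] += ds; total += ds;
        // Henyey-Greenstein deflection
        double ct;
        if (g == 0.0) ct = 2.0 * rng.u01() - 1.0;
        else {
          const double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.u01());
          ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
          if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
        }
        Y[lay] += 1.0 - ct;
        const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        const double phi = 2.0 * M_PI * rng.u01();
        const double cp = std::cos(phi), sp = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
        } else {
          const double den = std::sqrt(1.0 - uz * uz);
          const double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          const double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          const double nuz = -st * cp * den + uz * ct;
          ux = nux; uy = nuy; uz = nuz;
        }
        remaining = -std::log(rng.u01p());
      } else {
        // move to boundary
        x += ux * db; y += uy * db; z += uz * db;
        L[lay] += db; total += db;
        if (mus_l > 0.0) remaining -= db * mus_l;
        if (uz < 0.0 && lay == 0) {
          // top surface: Fresnel
          const double R = fresnel_R(n_in, n_out, -uz);
          if (rng.u01() < R) { uz = -uz; z = 0.0; }
          else {
            const double r = std::sqrt(x * x + y * y);
            if (r >= rho_min && r <= rho_max) detected = true;
            alive = false;
          }
        } else if (uz > 0.0) {
          if (zhi[lay] >= zmax) { alive = false; }  // exits bottom: lost
          else { ++lay; z = zhi[lay - 1]; }
        } else {
          --lay; z = zhi[lay];  // crosses up into the layer above
        }
      }
      if (alive) {
        if (total > max_path || x * x + y * y > rmax * rmax) alive = false;
      }
    }
    if (detected) {
      ++ndet;
      for (int i = 0; i < nl; ++i) Lrec.push_back(L[i]);
      for (int i = 0; i < nl; ++i) Yrec.push_back(Y[i]);
      Rrec.push_back(std::sqrt(x * x + y * y));
    }
  }

  NumericMatrix Lm(ndet, nl), Ym(ndet, nl);
  NumericVector rr(ndet);
  for (long long n = 0; n < ndet; ++n) {
    for (int i = 0; i < nl; ++i) {
      Lm(n, i) = Lrec[n * nl + i];
      Ym(n, i) = Yrec[n * nl + i];
    }
    rr[n] = Rrec[n];
  }
  return List::create(_["L"] = Lm, _["Y"] = Ym, _["exit_radius"] = rr,
                      _["n_launched"] = static_cast<double>(np),
                      _["n_detected"] = static_cast<double>(ndet));
}

// Ensemble field autocorrelation from per-photon tallies:
// G1(tau) = (1/Np) sum_n exp(-(1/3) k0^2 sum_i Y_ni * 6 Db_i * tau)
//                 * exp(-sum_i mua_i L_ni)
// evaluated for a vector of lags (tau = 0 gives the normalizer).

// [[Rcpp::export]]
NumericVector g1_records_cpp(NumericMatrix L, NumericMatrix Y,
                             NumericVector mua, NumericVector Db,
                             double k0, NumericVector tau) {
  const int np = L.nrow(), nl = L.ncol(), nt = tau.size();
  std::vector<double> wabs(np), ydb(np);
  for (int n = 0; n < np; ++n) {
    double a = 0.0, yd = 0.0;
    for (int i = 0; i < nl; ++i) {
      a += mua[i] * L(n, i);
      yd += Y(n, i) * Db[i];
    }
    wabs[n] = std::exp(-a);
    ydb[n] = 2.0 * k0 * k0 * yd;  // (1/3)*k0^2*6 = 2*k0^2
  }
  NumericVector out(nt);
  for (int j = 0; j < nt; ++j) {
    double acc = 0.0;
    for (int n = 0; n < np; ++n) acc += wabs[n] * std::exp(-ydb[n] * tau[j]);
    out[j] = acc / np;
  }
  return out;
}
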