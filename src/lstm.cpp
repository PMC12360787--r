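// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

// Stacked univariate-sequence LSTM with a dense scalar head, trained by BPTT
// with Adam. One bias vector per layer (4H), gate order [i; f; g; o]; the
// last timestep's top hidden state feeds the dense head. Dropout is applied
// between stacked layers (inverted, per-timestep masks). All randomness
// (init, shuffling, dropout) comes from one std::mt19937_64 per entry point,
// so runs are bit-reproducible for a given seed and thread count.

struct LstmWeights {
  std::vector<arma::mat> Wx, Wh;
  std::vector<arma::vec> b;
  arma::rowvec hw;
  double hb;
  int H, L;
};

static LstmWeights unpack(const List& w, int H, int L) {
  LstmWeights p; p.H = H; p.L = L;
  for (int l = 0; l < L; ++l) {
    p.Wx.push_back(as<arma::mat>(w[3 * l]));
    p.Wh.push_back(as<arma::mat>(w[3 * l + 1]));
    p.b.push_back(as<arma::vec>(w[3 * l + 2]));
  }
  p.hw = as<arma::rowvec>(w[3 * L]);
  p.hb = as<double>(w[3 * L + 1]);
  return p;
}

static List pack(const LstmWeights& p) {
  List out(3 * p.L + 2);
  for (int l = 0; l < p.L; ++l) {
    out[3 * l] = wrap(p.Wx[l]);
    out[3 * l + 1] = wrap(p.Wh[l]);
    out[3 * l + 2] = wrap(p.b[l]);
  }
  out[3 * p.L] = wrap(p.hw);
  out[3 * p.L + 1] = p.hb;
  return out;
}

// [[Rcpp::export]]
List lstm_init_cpp(int H, int L, int in_dim, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  const double k = 1.0 / std::sqrt(static_cast<double>(H));
  std::uniform_real_distribution<double> U(-k, k);
  auto fill = [&](arma::mat& M) { for (auto& v : M) v = U(rng); };
  LstmWeights p; p.H = H; p.L = L;
  for (int l = 0; l < L; ++l) {
    int in_l = (l == 0) ? in_dim : H;
    arma::mat Wx(4 * H, in_l), Wh(4 * H, H);
    fill(Wx); fill(Wh);
    arma::vec b(4 * H, arma::fill::zeros);
    b.subvec(H, 2 * H - 1).fill(1.0);  // forget-gate bias at 1
    p.Wx.push_back(Wx); p.Wh.push_back(Wh); p.b.push_back(b);
  }
  arma::mat hw(1, H); fill(hw);
  p.hw = hw.row(0);
  p.hb = 0.0;
  return pack(p);
}

static inline arma::mat sigm(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// forward pass, optionally caching activations for BPTT
struct Cache {
  // [layer][t]
  std::vector<std::vector<arma::mat>> I, F, G, O, C, Hs, Xin, Mask;
};

static arma::rowvec forward(const LstmWeights& p, const arma::mat& Xb,
                            double dropout, bool train, std::mt19937_64* rng,
                            Cache* cache) {
  const int B = Xb.n_rows, T = Xb.n_cols, H = p.H, L = p.L;
  arma::mat input;  // (features x B) per timestep handled inside loop
  std::vector<arma::mat> h(L), c(L);
  for (int l = 0; l < L; ++l) {
    h[l] = arma::mat(H, B, arma::fill::zeros);
    c[l] = arma::mat(H, B, arma::fill::zeros);
  }
  if (cache) {
    cache->I.assign(L, {}); cache->F.assign(L, {}); cache->G.assign(L, {});
    cache->O.assign(L, {}); cache->C.assign(L, {}); cache->Hs.assign(L, {});
    cache->Xin.assign(L, {}); cache->Mask.assign(L, {});
  }
  std::uniform_real_distribution<double> U(0.0, 1.0);
  for (int t = 0; t < T; ++t) {
    arma::mat x = Xb.col(t).t();  // 1 x B
    for (int l = 0; l < L; ++l) {
      arma::mat xin = (l == 0) ? x : input;
      if (l > 0 && dropout > 0.0 && train) {
        arma::mat mask(H, B);
        for (auto& m : mask) m = (U(*rng) >= dropout) ? 1.0 : 0.0;
        xin = xin % mask / (1.0 - dropout);
        if (cache) cache->Mask[l].push_back(mask);
      }
      arma::mat a = p.Wx[l] * xin + p.Wh[l] * h[l];
      a.each_col() += p.b[l];
      arma::mat gi = sigm(a.rows(0, H - 1));
      arma::mat gf = sigm(a.rows(H, 2 * H - 1));
      arma::mat gg = arma::tanh(a.rows(2 * H, 3 * H - 1));
      arma::mat go = sigm(a.rows(3 * H, 4 * H - 1));
      arma::mat cn = gf % c[l] + gi % gg;
      arma::mat hn = go % arma::tanh(cn);
      if (cache) {
        cache->I[l].push_back(gi); cache->F[l].push_back(gf);
        cache->G[l].push_back(gg); cache->O[l].push_back(go);
        cache->C[l].push_back(cn); cache->Hs[l].push_back(hn);
        cache->Xin[l].push_back(xin);
      }
      c[l] = cn; h[l] = hn;
      input = hn;
    }
  }
  return p.hw * h[L - 1] + p.hb;  // 1 x B
}

struct Grads {
  std::vector<arma::mat> Wx, Wh;
  std::vector<arma::vec> b;
  arma::rowvec hw;
  double hb;
};

static void backward(const LstmWeights& p, const Cache& cc, const arma::mat& Xb,
                     const arma::rowvec& dyhat, double dropout, Grads& g) {
  const int B = Xb.n_rows, T = Xb.n_cols, H = p.H, L = p.L;
  g.Wx.clear(); g.Wh.clear(); g.b.clear();
  for (int l = 0; l < L; ++l) {
    g.Wx.push_back(arma::mat(arma::size(p.Wx[l]), arma::fill::zeros));
    g.Wh.push_back(arma::mat(arma::size(p.Wh[l]), arma::fill::zeros));
    g.b.push_back(arma::vec(4 * H, arma::fill::zeros));
  }
  g.hw = p.hw * 0.0; g.hb = 0.0;

  // head
  g.hw = dyhat * cc.Hs[L - 1][T - 1].t();
  g.hb = arma::accu(dyhat);

  // dh injected from above, per layer per t
  std::vector<std::vector<arma::mat>> dtop(L);
  for (int l = 0; l < L; ++l)
    dtop[l].assign(T, arma::mat(H, B, arma::fill::zeros));
  dtop[L - 1][T - 1] = p.hw.t() * dyhat;

  for (int l = L - 1; l >= 0; --l) {
    arma::mat dh_rec(H, B, arma::fill::zeros), dc_rec(H, B, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      arma::mat dh = dtop[l][t] + dh_rec;
      arma::mat th = arma::tanh(cc.C[l][t]);
      arma::mat dc = dc_rec + dh % cc.O[l][t] % (1.0 - th % th);
      arma::mat cprev = (t == 0) ? arma::mat(H, B, arma::fill::zeros)
                                 : cc.C[l][t - 1];
      arma::mat hprev = (t == 0) ? arma::mat(H, B, arma::fill::zeros)
                                 : cc.Hs[l][t - 1];
      arma::mat dai = (dc % cc.G[l][t]) % cc.I[l][t] % (1.0 - cc.I[l][t]);
      arma::mat daf = (dc % cprev) % cc.F[l][t] % (1.0 - cc.F[l][t]);
      arma::mat dag = (dc % cc.I[l][t]) % (1.0 - cc.G[l][t] % cc.G[l][t]);
      arma::mat dao = (dh % th) % cc.O[l][t] % (1.0 - cc.O[l][t]);
      arma::mat da = arma::join_cols(arma::join_cols(dai, daf),
                                     arma::join_cols(dag, dao));
      g.Wx[l] += da * cc.Xin[l][t].t();
      g.Wh[l] += da * hprev.t();
      g.b[l] += arma::sum(da, 1);
      dh_rec = p.Wh[l].t() * da;
      dc_rec = dc % cc.F[l][t];
      if (l > 0) {
        arma::mat dx = p.Wx[l].t() * da;
        if (dropout > 0.0 && !cc.Mask[l].empty())
          dx = dx % cc.Mask[l][t] / (1.0 - dropout);
        dtop[l - 1][t] += dx;
      }
    }
  }
}

// [[Rcpp::export]]
List lstm_train_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                    const arma::mat& Xval, const arma::vec& yval,
                    List weights, int H, int L,
                    int epochs, int batch_size, double lr,
                    double weight_decay, double dropout, double clipnorm,
                    int seed) {
  LstmWeights p = unpack(weights, H, L);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  const int n = Xtr.n_rows;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  // Adam state, flat order: Wx/Wh/b per layer then hw, hb
  std::vector<arma::mat> mWx(L), vWx(L), mWh(L), vWh(L);
  std::vector<arma::vec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    mWx[l] = arma::mat(arma::size(p.Wx[l]), arma::fill::zeros); vWx[l] = mWx[l];
    mWh[l] = arma::mat(arma::size(p.Wh[l]), arma::fill::zeros); vWh[l] = mWh[l];
    mb[l] = arma::vec(4 * H, arma::fill::zeros); vb[l] = mb[l];
  }
  arma::rowvec mhw = p.hw * 0.0, vhw = p.hw * 0.0;
  double mhb = 0.0, vhb = 0.0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  arma::vec train_loss(epochs), val_loss(epochs);
  Grads g;
  Cache cc;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double sse = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(start + batch_size, n);
      const int B = end - start;
      arma::mat Xb(B, Xtr.n_cols);
      arma::rowvec yb(B);
      for (int i = 0; i < B; ++i) {
        Xb.row(i) = Xtr.row(idx[start + i]);
        yb[i] = ytr[idx[start + i]];
      }
      arma::rowvec yhat = forward(p, Xb, dropout, true, &rng, &cc);
      arma::rowvec err = yhat - yb;
      sse += arma::accu(err % err);
      arma::rowvec dyhat = 2.0 * err / B;
      backward(p, cc, Xb, dyhat, dropout, g);
      // L2 on weight matrices (not biases)
      for (int l = 0; l < L; ++l) {
        g.Wx[l] += weight_decay * p.Wx[l];
        g.Wh[l] += weight_decay * p.Wh[l];
      }
      g.hw += weight_decay * p.hw;
      // global-norm clip
      double nrm2 = arma::accu(arma::square(g.hw)) + g.hb * g.hb;
      for (int l = 0; l < L; ++l)
        nrm2 += arma::accu(arma::square(g.Wx[l])) +
                arma::accu(arma::square(g.Wh[l])) +
                arma::accu(arma::square(g.b[l]));
      const double nrm = std::sqrt(nrm2);
      const double sc = (clipnorm > 0.0 && nrm > clipnorm) ? clipnorm / nrm : 1.0;
      ++step;
      const double bc1 = 1.0 - std::pow(b1, step);
      const double bc2 = 1.0 - std::pow(b2, step);
      auto adam = [&](arma::mat& w, arma::mat& m, arma::mat& v, const arma::mat& gr) {
        m = b1 * m + (1.0 - b1) * (sc * gr);
        v = b2 * v + (1.0 - b2) * arma::square(sc * gr);
        w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
      };
      for (int l = 0; l < L; ++l) {
        adam(p.Wx[l], mWx[l], vWx[l], g.Wx[l]);
        adam(p.Wh[l], mWh[l], vWh[l], g.Wh[l]);
        arma::vec gb = sc * g.b[l];
        mb[l] = b1 * mb[l] + (1.0 - b1) * gb;
        vb[l] = b2 * vb[l] + (1.0 - b2) * arma::square(gb);
        p.b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
      {
        arma::rowvec ghw = sc * g.hw;
        mhw = b1 * mhw + (1.0 - b1) * ghw;
        vhw = b2 * vhw + (1.0 - b2) * arma::square(ghw);
        p.hw -= lr * (mhw / bc1) / (arma::sqrt(vhw / bc2) + eps);
        const double ghb = sc * g.hb;
        mhb = b1 * mhb + (1.0 - b1) * ghb;
        vhb = b2 * vhb + (1.0 - b2) * ghb * ghb;
        p.hb -= lr * (mhb / bc1) / (std::sqrt(vhb / bc2) + eps);
      }
      if (!std::isfinite(sse)) stop("training diverged (non-finite loss)");
    }
    train_loss[ep] = sse / n;
    if (Xval.n_rows > 0) {
      arma::rowvec yv = forward(p, Xval, 0.0, false, nullptr, nullptr);
      arma::rowvec ev = yv - yval.t();
      val_loss[ep] = arma::accu(ev % ev) / Xval.n_rows;
    } else {
      val_loss[ep] = NA_REAL;
    }
  }
  return List::create(_["weights"] = pack(p),
                      _["train_loss"] = wrap(train_loss),
                      _["val_loss"] = wrap(val_loss));
}

// analytic MSE gradient for verification against finite differences
// [[Rcpp::export]]
List lstm_grad_cpp(const arma::mat& X, const arma::vec& y, List weights,
                   int H, int L) {
  LstmWeights p = unpack(weights, H, L);
  Cache cc;
  arma::rowvec yhat = forward(p, X, 0.0, false, nullptr, &cc);
  arma::rowvec dyhat = 2.0 * (yhat - y.t()) / X.n_rows;
  Grads g;
  backward(p, cc, X, dyhat, 0.0, g);
  List out(3 * L + 2);
  for (int l = 0; l < L; ++l) {
    out[3 * l] = wrap(g.Wx[l]);
    out[3 * l + 1] = wrap(g.Wh[l]);
    out[3 * l + 2] = wrap(g.b[l]);
  }
  out[3 * L] = wrap(g.hw);
  out[3 * L + 1] = g.hb;
  return out;
}

// [[Rcpp::export]]
NumericVector lstm_predict_cpp(const arma::mat& X, List weights, int H, int L) {
  LstmWeights p = unpack(weights, H, L);
  arma::rowvec yhat = forward(p, X, 0.0, false, nullptr, nullptr);
  return wrap(arma::vec(yhat.t()));
}
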