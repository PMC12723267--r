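// Whole-network forward/backward training step in C++.  The R level keeps a
// readable layer-by-layer reference implementation; this file exists so a
// minibatch crosses the R/C++ boundary once instead of per layer (feature
// maps stay native, only parameters and gradients are converted).
// Semantics match the R layers exactly; a test cross-checks the two paths.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

// from nn_kernels.cpp
arma::cube conv_fw(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                   int H, int Wd, int k);
arma::cube conv_bw_impl(const arma::cube& x, const arma::mat& W,
                        const arma::cube& dy, int H, int Wd, int k,
                        arma::mat& dW, arma::vec& db);
arma::cube maxpool3_fw_impl(const arma::cube& x, int H, int Wd,
                            arma::ucube& idx);
arma::cube maxpool3_bw(const arma::cube& dy, const arma::ucube& idx);

static const double BN_EPS = 1e-3;
static const double BN_MOM = 0.9;

struct ConvP { arma::mat W; arma::vec b; int k; };
struct BNP { arma::vec gamma, beta, rmean, rvar; };
struct FEBP { ConvP c1, c2; BNP bn1, bn2; };
struct FusionP { FEBP f1, f3, f5; ConvP pc; };
struct DenseP { arma::mat W; arma::vec b; };
struct CABP { arma::mat W1, W2; arma::vec b1, b2; };

static ConvP getConv(const Rcpp::List& l) {
  ConvP p; p.W = Rcpp::as<arma::mat>(l["W"]); p.b = Rcpp::as<arma::vec>(l["b"]);
  p.k = Rcpp::as<int>(l["k"]); return p;
}
static BNP getBN(const Rcpp::List& l) {
  BNP p; p.gamma = Rcpp::as<arma::vec>(l["gamma"]);
  p.beta = Rcpp::as<arma::vec>(l["beta"]);
  p.rmean = Rcpp::as<arma::vec>(l["rmean"]);
  p.rvar = Rcpp::as<arma::vec>(l["rvar"]); return p;
}
static FEBP getFEB(const Rcpp::List& l) {
  FEBP p; p.c1 = getConv(l["conv1"]); p.bn1 = getBN(l["bn1"]);
  p.c2 = getConv(l["conv2"]); p.bn2 = getBN(l["bn2"]); return p;
}
static FusionP getFusion(const Rcpp::List& l) {
  FusionP p; p.f1 = getFEB(l["feb1"]); p.f3 = getFEB(l["feb3"]);
  p.f5 = getFEB(l["feb5"]); p.pc = getConv(l["poolconv"]); return p;
}
static DenseP getDense(const Rcpp::List& l) {
  DenseP p; p.W = Rcpp::as<arma::mat>(l["W"]); p.b = Rcpp::as<arma::vec>(l["b"]);
  return p;
}
static CABP getCAB(const Rcpp::List& l) {
  CABP p; p.W1 = Rcpp::as<arma::mat>(l["W1"]); p.b1 = Rcpp::as<arma::vec>(l["b1"]);
  p.W2 = Rcpp::as<arma::mat>(l["W2"]); p.b2 = Rcpp::as<arma::vec>(l["b2"]);
  return p;
}

// ---- primitive forward/backward (internal, cube-native) --------------------

struct BNCache { arma::cube x, y; arma::vec mu, ivstd; };

static arma::cube bnrelu_fw(const BNP& p, arma::cube&& x, bool training,
                            BNCache& cache, arma::vec& nrm, arma::vec& nrv,
                            bool relu = true) {
  const int C = x.n_cols, B = x.n_slices;
  const size_t HW = x.n_rows;
  const double m = (double)HW * B;
  arma::vec mu(C), var(C);
  if (training) {
    mu.zeros(); var.zeros();
    for (int s = 0; s < B; ++s) {
      mu += arma::sum(x.slice(s), 0).t();
      var += arma::sum(arma::square(x.slice(s)), 0).t();
    }
    mu /= m;
    var = var / m - arma::square(mu);
    var.transform([](double v) { return v < 0 ? 0 : v; });
    nrm = BN_MOM * p.rmean + (1 - BN_MOM) * mu;
    nrv = BN_MOM * p.rvar + (1 - BN_MOM) * var * m / std::max(m - 1, 1.0);
  } else {
    mu = p.rmean; var = p.rvar;
    nrm = p.rmean; nrv = p.rvar;
  }
  arma::vec ivstd = 1.0 / arma::sqrt(var + BN_EPS);
  arma::cube y(arma::size(x));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(s).colptr(c);
      double* yc = y.slice(s).colptr(c);
      const double a = p.gamma(c) * ivstd(c);
      const double d = p.beta(c) - a * mu(c);
      if (relu)
        for (size_t q = 0; q < HW; ++q) {
          const double v = a * xc[q] + d;
          yc[q] = v > 0 ? v : 0;
        }
      else
        for (size_t q = 0; q < HW; ++q) yc[q] = a * xc[q] + d;
    }
  cache.x = std::move(x);
  cache.y = y;  // copy kept for the ReLU mask / next layer input
  cache.mu = mu; cache.ivstd = ivstd;
  return y;
}

static arma::cube bnrelu_bw(const BNP& p, const BNCache& cache,
                            const arma::cube& dy, arma::vec& dgamma,
                            arma::vec& dbeta, bool relu = true) {
  const int C = cache.x.n_cols, B = cache.x.n_slices;
  const size_t HW = cache.x.n_rows;
  const double m = (double)HW * B;
  arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* xc = cache.x.slice(s).colptr(c);
      const double* yc = cache.y.slice(s).colptr(c);
      const double* g = dy.slice(s).colptr(c);
      double a1 = 0, a2 = 0;
      for (size_t q = 0; q < HW; ++q) {
        const double gd = (relu && yc[q] <= 0) ? 0 : g[q];
        a1 += gd;
        a2 += gd * (xc[q] - cache.mu(c)) * cache.ivstd(c);
      }
      s1(c) += a1; s2(c) += a2;
    }
  arma::cube dx(arma::size(cache.x));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* xc = cache.x.slice(s).colptr(c);
      const double* yc = cache.y.slice(s).colptr(c);
      const double* g = dy.slice(s).colptr(c);
      double* d = dx.slice(s).colptr(c);
      const double a = p.gamma(c) * cache.ivstd(c) / m;
      for (size_t q = 0; q < HW; ++q) {
        const double gd = (relu && yc[q] <= 0) ? 0 : g[q];
        const double xh = (xc[q] - cache.mu(c)) * cache.ivstd(c);
        d[q] = a * (m * gd - s1(c) - xh * s2(c));
      }
    }
  dgamma = s2; dbeta = s1;
  return dx;
}

// conv helpers reusing the exported kernels
static arma::cube cfw(const ConvP& p, const arma::cube& x) {
  return conv_fw(x, p.W, p.b, 64, 64, p.k);
}
struct ConvGrad { arma::mat dW; arma::vec db; };
static arma::cube cbw(const ConvP& p, const arma::cube& x,
                      const arma::cube& dy, ConvGrad& g) {
  return conv_bw_impl(x, p.W, dy, 64, 64, p.k, g.dW, g.db);
}

struct FEBCache { BNCache b1, b2; };
struct FEBStats { arma::vec rm1, rv1, rm2, rv2; };
struct FEBGrad { ConvGrad c1, c2; arma::vec g1, be1, g2, be2; };

// x is not stored here; the caller keeps it and passes it to feb_bw.
static arma::cube feb_fw(const FEBP& p, const arma::cube& x, bool training,
                         FEBCache& cache, FEBStats& st) {
  arma::cube c1 = cfw(p.c1, x);
  arma::cube y1 = bnrelu_fw(p.bn1, std::move(c1), training, cache.b1,
                            st.rm1, st.rv1);
  arma::cube c2 = cfw(p.c2, y1);
  return bnrelu_fw(p.bn2, std::move(c2), training, cache.b2, st.rm2, st.rv2);
}

static arma::cube feb_bw(const FEBP& p, const arma::cube& x,
                         const FEBCache& cache, const arma::cube& dy,
                         FEBGrad& g) {
  arma::cube d2 = bnrelu_bw(p.bn2, cache.b2, dy, g.g2, g.be2);
  arma::cube d1 = cbw(p.c2, cache.b1.y, d2, g.c2);
  arma::cube d0 = bnrelu_bw(p.bn1, cache.b1, d1, g.g1, g.be1);
  return cbw(p.c1, x, d0, g.c1);
}

struct FusionCache {
  arma::cube x;            // block input (owned here)
  FEBCache f1, f3, f5;
  arma::ucube mpIdx;
  arma::cube mpY;          // pooled map (input of the 1x1 conv)
  arma::cube prY;          // ReLU output of the pooled branch
  int nb[4];
};
struct FusionStats { FEBStats f1, f3, f5; };
struct FusionGrad { FEBGrad f1, f3, f5; ConvGrad pc; };

static arma::cube fusion_fw(const FusionP& p, arma::cube&& x, bool training,
                            FusionCache& cache, FusionStats& st) {
  cache.x = std::move(x);
  arma::cube y1 = feb_fw(p.f1, cache.x, training, cache.f1, st.f1);
  arma::cube y3 = feb_fw(p.f3, cache.x, training, cache.f3, st.f3);
  arma::cube y5 = feb_fw(p.f5, cache.x, training, cache.f5, st.f5);
  cache.mpY = maxpool3_fw_impl(cache.x, 64, 64, cache.mpIdx);
  arma::cube pc = cfw(p.pc, cache.mpY);
  cache.prY = arma::clamp(pc, 0.0, arma::datum::inf);
  const int B = cache.x.n_slices;
  cache.nb[0] = y1.n_cols; cache.nb[1] = y3.n_cols;
  cache.nb[2] = y5.n_cols; cache.nb[3] = cache.prY.n_cols;
  arma::cube y(cache.x.n_rows,
               cache.nb[0] + cache.nb[1] + cache.nb[2] + cache.nb[3], B);
  for (int s = 0; s < B; ++s) {
    int off = 0;
    y.slice(s).cols(off, off + cache.nb[0] - 1) = y1.slice(s); off += cache.nb[0];
    y.slice(s).cols(off, off + cache.nb[1] - 1) = y3.slice(s); off += cache.nb[1];
    y.slice(s).cols(off, off + cache.nb[2] - 1) = y5.slice(s); off += cache.nb[2];
    y.slice(s).cols(off, off + cache.nb[3] - 1) = cache.prY.slice(s);
  }
  return y;
}

static arma::cube fusion_bw(const FusionP& p, const FusionCache& cache,
                            const arma::cube& dy, FusionGrad& g) {
  const int B = cache.x.n_slices;
  const size_t HW = cache.x.n_rows;
  auto part = [&](int block) {
    int off = 0;
    for (int i = 0; i < block; ++i) off += cache.nb[i];
    arma::cube d(HW, cache.nb[block], B);
    for (int s = 0; s < B; ++s)
      d.slice(s) = dy.slice(s).cols(off, off + cache.nb[block] - 1);
    return d;
  };
  arma::cube dx = feb_bw(p.f1, cache.x, cache.f1, part(0), g.f1);
  dx += feb_bw(p.f3, cache.x, cache.f3, part(1), g.f3);
  dx += feb_bw(p.f5, cache.x, cache.f5, part(2), g.f5);
  arma::cube dpr = part(3);
  dpr.elem(arma::find(cache.prY <= 0)).zeros();
  arma::cube dmp = cbw(p.pc, cache.mpY, dpr, g.pc);
  dx += maxpool3_bw(dmp, cache.mpIdx);
  return dx;
}

struct CABCache { arma::cube x; arma::mat z, a1, w; arma::umat maxIdx; };
struct CABGrad { arma::mat dW1, dW2; arma::vec db1, db2; };

static arma::cube cab_fw(const CABP& p, arma::cube&& x, CABCache& cache) {
  const int C = x.n_cols, B = x.n_slices;
  const size_t HW = x.n_rows;
  arma::mat zavg(C, B), zmax(C, B);
  arma::umat idx(C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      zavg(c, s) = arma::mean(x.slice(s).col(c));
      arma::uword bi;
      zmax(c, s) = x.slice(s).col(c).max(bi);
      idx(c, s) = bi;
    }
  arma::mat z = zavg + zmax;
  arma::mat h1 = p.W1.t() * z;
  h1.each_col() += p.b1;
  arma::mat a1 = arma::clamp(h1, 0.0, arma::datum::inf);
  arma::mat u = p.W2.t() * a1;
  u.each_col() += p.b2;
  arma::mat w = 1.0 / (1.0 + arma::exp(-u));
  arma::cube y(arma::size(x));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      y.slice(s).col(c) = w(c, s) * x.slice(s).col(c);
  cache.x = std::move(x); cache.z = z; cache.a1 = a1; cache.w = w;
  cache.maxIdx = idx;
  return y;
}

static arma::cube cab_bw(const CABP& p, const CABCache& cache,
                         const arma::cube& dy, CABGrad& g) {
  const int C = cache.x.n_cols, B = cache.x.n_slices;
  const size_t HW = cache.x.n_rows;
  arma::mat dw(C, B);
  arma::cube dx(arma::size(cache.x));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      dw(c, s) = arma::dot(dy.slice(s).col(c), cache.x.slice(s).col(c));
      dx.slice(s).col(c) = cache.w(c, s) * dy.slice(s).col(c);
    }
  arma::mat du = dw % cache.w % (1.0 - cache.w);
  g.dW2 = cache.a1 * du.t();
  g.db2 = arma::sum(du, 1);
  arma::mat da1 = p.W2 * du;
  arma::mat dh1 = da1;
  dh1.elem(arma::find(cache.a1 <= 0)).zeros();
  g.dW1 = cache.z * dh1.t();
  g.db1 = arma::sum(dh1, 1);
  arma::mat dz = p.W1 * dh1;
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      dx.slice(s).col(c) += dz(c, s) / (double)HW;
      dx.slice(s)(cache.maxIdx(c, s), c) += dz(c, s);
    }
  return dx;
}

// ---- whole-network step ----------------------------------------------------

static Rcpp::List convGradList(const ConvGrad& g) {
  return Rcpp::List::create(Rcpp::Named("W") = g.dW, Rcpp::Named("b") = g.db);
}
static Rcpp::List febGradList(const FEBGrad& g) {
  return Rcpp::List::create(
    Rcpp::Named("conv1") = convGradList(g.c1),
    Rcpp::Named("bn1") = Rcpp::List::create(Rcpp::Named("gamma") = g.g1,
                                            Rcpp::Named("beta") = g.be1),
    Rcpp::Named("conv2") = convGradList(g.c2),
    Rcpp::Named("bn2") = Rcpp::List::create(Rcpp::Named("gamma") = g.g2,
                                            Rcpp::Named("beta") = g.be2));
}
static Rcpp::List fusionGradList(const FusionGrad& g) {
  return Rcpp::List::create(
    Rcpp::Named("feb1") = febGradList(g.f1),
    Rcpp::Named("feb3") = febGradList(g.f3),
    Rcpp::Named("feb5") = febGradList(g.f5),
    Rcpp::Named("poolconv") = convGradList(g.pc));
}
static Rcpp::List bnStatList(const arma::vec& rm, const arma::vec& rv) {
  return Rcpp::List::create(Rcpp::Named("rmean") = rm, Rcpp::Named("rvar") = rv);
}
static Rcpp::List febStatList(const FEBStats& s) {
  return Rcpp::List::create(Rcpp::Named("bn1") = bnStatList(s.rm1, s.rv1),
                            Rcpp::Named("bn2") = bnStatList(s.rm2, s.rv2));
}
static Rcpp::List fusionStatList(const FusionStats& s) {
  return Rcpp::List::create(Rcpp::Named("feb1") = febStatList(s.f1),
                            Rcpp::Named("feb3") = febStatList(s.f3),
                            Rcpp::Named("feb5") = febStatList(s.f5));
}

// One training/evaluation pass.  When Y has size 0 only the forward pass
// runs.  variant/nFusion come from the architecture config.
// [[Rcpp::export(name = ".cafnet_pass")]]
Rcpp::List cafnet_pass(const Rcpp::List& params, const arma::mat& X,
                       const arma::cube& Y, const arma::vec& lossWeights,
                       const std::string& variant, int nFusion,
                       bool training, bool withGrads, bool withMaps) {
  const int B = X.n_cols;
  const bool hasFEB = variant != "no_feb";
  const bool hasFusion = variant != "feb_only";
  const bool hasCAB = variant == "full" || variant == "no_feb";

  DenseP fc1 = getDense(params["fc1"]), fc2 = getDense(params["fc2"]);
  // automap: two fully connected tanh layers
  arma::mat h1 = fc1.W.t() * X; h1.each_col() += fc1.b; h1 = arma::tanh(h1);
  arma::mat h2 = fc2.W.t() * h1; h2.each_col() += fc2.b; h2 = arma::tanh(h2);
  arma::cube x(4096, 1, B);
  for (int s = 0; s < B; ++s) x.slice(s).col(0) = h2.col(s);
  arma::cube automapOut;
  if (withMaps) automapOut = x;

  FEBP feb0; FEBCache feb0Cache; FEBStats feb0Stats;
  arma::cube feb0In;
  if (hasFEB) {
    feb0 = getFEB(params["feb0"]);
    feb0In = x;
    x = feb_fw(feb0, feb0In, training, feb0Cache, feb0Stats);
  }
  std::vector<FusionP> fus(nFusion);
  std::vector<FusionCache> fusCache(nFusion);
  std::vector<FusionStats> fusStats(nFusion);
  if (hasFusion)
    for (int i = 0; i < nFusion; ++i) {
      fus[i] = getFusion(params["fusion" + std::to_string(i + 1)]);
      x = fusion_fw(fus[i], std::move(x), training, fusCache[i], fusStats[i]);
    }
  CABP cab; CABCache cabCache;
  arma::cube preCAB, postCAB;
  if (hasCAB) {
    cab = getCAB(params["cab"]);
    if (withMaps) preCAB = x;
    x = cab_fw(cab, std::move(x), cabCache);
    if (withMaps) postCAB = x;
  }
  ConvP out = getConv(params["out"]);
  arma::cube y = cfw(out, x);   // x now holds the output-head input

  Rcpp::List res;
  res["y"] = y;
  if (hasCAB) res["attWeights"] = cabCache.w;
  if (withMaps) {
    res["automap"] = automapOut;
    if (hasCAB) { res["preCAB"] = preCAB; res["postCAB"] = postCAB; }
  }
  if (Y.n_elem == 0) return res;

  // weighted two-channel MSE
  const double n = 4096.0 * B;
  double l1 = 0, l2 = 0;
  arma::cube dOut(arma::size(y));
  for (int s = 0; s < B; ++s) {
    arma::vec d1 = y.slice(s).col(0) - Y.slice(s).col(0);
    arma::vec d2 = y.slice(s).col(1) - Y.slice(s).col(1);
    l1 += arma::dot(d1, d1); l2 += arma::dot(d2, d2);
    dOut.slice(s).col(0) = 2.0 * lossWeights(0) * d1 / n;
    dOut.slice(s).col(1) = 2.0 * lossWeights(1) * d2 / n;
  }
  l1 /= n; l2 /= n;
  res["loss"] = lossWeights(0) * l1 + lossWeights(1) * l2;
  res["channelMSE"] = Rcpp::NumericVector::create(l1, l2);
  if (!withGrads) return res;

  Rcpp::List grads;
  ConvGrad gOut;
  arma::cube dx = cbw(out, x, dOut, gOut);
  grads["out"] = convGradList(gOut);
  if (hasCAB) {
    CABGrad gCab;
    dx = cab_bw(cab, cabCache, dx, gCab);
    grads["cab"] = Rcpp::List::create(
      Rcpp::Named("W1") = gCab.dW1, Rcpp::Named("b1") = gCab.db1,
      Rcpp::Named("W2") = gCab.dW2, Rcpp::Named("b2") = gCab.db2);
  }
  Rcpp::List stats;
  if (hasFusion)
    for (int i = nFusion - 1; i >= 0; --i) {
      FusionGrad gF;
      dx = fusion_bw(fus[i], fusCache[i], dx, gF);
      grads["fusion" + std::to_string(i + 1)] = fusionGradList(gF);
      stats["fusion" + std::to_string(i + 1)] = fusionStatList(fusStats[i]);
    }
  if (hasFEB) {
    FEBGrad gFeb;
    dx = feb_bw(feb0, feb0In, feb0Cache, dx, gFeb);
    grads["feb0"] = febGradList(gFeb);
    stats["feb0"] = febStatList(feb0Stats);
  }
  // dense backward (tanh chain)
  arma::mat dflat(4096, B);
  for (int s = 0; s < B; ++s) dflat.col(s) = dx.slice(s).col(0);
  dflat %= (1.0 - arma::square(h2));
  arma::mat dW2 = h1 * dflat.t();
  arma::vec db2 = arma::sum(dflat, 1);
  arma::mat dh1 = fc2.W * dflat;
  dh1 %= (1.0 - arma::square(h1));
  arma::mat dW1 = X * dh1.t();
  arma::vec db1 = arma::sum(dh1, 1);
  grads["fc2"] = Rcpp::List::create(Rcpp::Named("W") = dW2, Rcpp::Named("b") = db2);
  grads["fc1"] = Rcpp::List::create(Rcpp::Named("W") = dW1, Rcpp::Named("b") = db1);
  res["grads"] = grads;
  res["stats"] = stats;
  return res;
}
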