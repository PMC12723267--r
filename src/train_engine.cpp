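// Single-precision training engine: runs the whole minibatch-Adam loop for
// the reconstruction network inside one call, so no feature map or gradient
// ever crosses the R boundary during training.  Parameters arrive as the R
// parameter list (double), train in float (the customary precision for
// convolutional network training), and return as the same R structure.
// The double-precision graph pass (cafnet_step.cpp) and the R layer
// implementation remain the reference paths; tests cross-check all three.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

typedef arma::fmat FM;
typedef arma::fvec FV;
typedef arma::fcube FC;
typedef arma::ucube UC;

static const float F_BN_EPS = 1e-3f;
static const float F_BN_MOM = 0.9f;

// ---- float im2col convolution ---------------------------------------------

static void f_im2col(const float* xc, int H, int W, int k, int pad,
                     float* col) {
  const size_t HW = (size_t)H * W;
  int t = 0;
  for (int v = 0; v < k; ++v)
    for (int u = 0; u < k; ++u, ++t) {
      float* dst = col + (size_t)t * HW;
      const int du = u - pad, dv = v - pad;
      const int lo = du < 0 ? -du : 0;
      const int hi = du > 0 ? H - du : H;
      for (int j = 0; j < W; ++j) {
        const int sj = j + dv;
        float* d = dst + (size_t)j * H;
        if (sj < 0 || sj >= W) { std::memset(d, 0, sizeof(float) * H); continue; }
        const float* s = xc + (size_t)sj * H;
        if (lo > 0) std::memset(d, 0, sizeof(float) * lo);
        std::memcpy(d + lo, s + lo + du, sizeof(float) * (hi - lo));
        if (hi < H) std::memset(d + hi, 0, sizeof(float) * (H - hi));
      }
    }
}

static void f_build_col(const float* xs, int Cin, int H, int W, int k, FM& col) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < Cin; ++c)
    f_im2col(xs + (size_t)c * HW, H, W, k, pad, col.colptr((size_t)c * k * k));
}

struct FConv {
  FM W; FV b; int k;
  FM dW, mW, vW; FV db, mb, vb;
  void initState() {
    dW.zeros(W.n_rows, W.n_cols); mW.zeros(W.n_rows, W.n_cols);
    vW.zeros(W.n_rows, W.n_cols);
    db.zeros(b.n_elem); mb.zeros(b.n_elem); vb.zeros(b.n_elem);
  }
};

static FC f_conv_fw(const FConv& p, const FC& x) {
  const int B = x.n_slices, Cin = x.n_cols, Cout = p.W.n_cols, k = p.k;
  const size_t HW = x.n_rows;
  FC y(HW, Cout, B);
  if (k == 1) {
    for (int s = 0; s < B; ++s) {
      y.slice(s) = x.slice(s) * p.W;
      y.slice(s).each_row() += p.b.t();
    }
    return y;
  }
  FM col(HW, (size_t)Cin * k * k);
  for (int s = 0; s < B; ++s) {
    f_build_col(x.slice(s).memptr(), Cin, 64, 64, k, col);
    y.slice(s) = col * p.W;
    y.slice(s).each_row() += p.b.t();
  }
  return y;
}

// accumulates dW/db into p; returns dx
static FC f_conv_bw(FConv& p, const FC& x, const FC& dy) {
  const int B = x.n_slices, Cin = x.n_cols, Cout = p.W.n_cols, k = p.k;
  const int kk = k * k;
  const size_t HW = x.n_rows;
  p.dW.zeros(); p.db.zeros();
  FC dx(HW, Cin, B);
  if (k == 1) {
    for (int s = 0; s < B; ++s) {
      p.dW += x.slice(s).t() * dy.slice(s);
      p.db += arma::sum(dy.slice(s), 0).t();
      dx.slice(s) = dy.slice(s) * p.W.t();
    }
    return dx;
  }
  FM Wr((size_t)Cout * kk, Cin);
  for (int cin = 0; cin < Cin; ++cin)
    for (int t = 0; t < kk; ++t)
      for (int cout = 0; cout < Cout; ++cout)
        Wr((size_t)cout * kk + (kk - 1 - t), cin) = p.W((size_t)cin * kk + t, cout);
  FM col(HW, (size_t)Cin * kk), dcol(HW, (size_t)Cout * kk);
  for (int s = 0; s < B; ++s) {
    f_build_col(x.slice(s).memptr(), Cin, 64, 64, k, col);
    p.dW += col.t() * dy.slice(s);
    p.db += arma::sum(dy.slice(s), 0).t();
    f_build_col(dy.slice(s).memptr(), Cout, 64, 64, k, dcol);
    dx.slice(s) = dcol * Wr;
  }
  return dx;
}

// ---- batch norm (+ fused ReLU) --------------------------------------------

struct FBN {
  FV gamma, beta, rmean, rvar;
  FV dgamma, dbeta, mg, vg, mbe, vbe;
  void initState() {
    const int C = gamma.n_elem;
    dgamma.zeros(C); dbeta.zeros(C); mg.zeros(C); vg.zeros(C);
    mbe.zeros(C); vbe.zeros(C);
  }
};

struct FBNCache { FC x, y; FV mu, ivstd; };

static FC f_bnrelu_fw(FBN& p, FC&& x, bool training, FBNCache& cache) {
  const int C = x.n_cols, B = x.n_slices;
  const size_t HW = x.n_rows;
  const double m = (double)HW * B;
  FV mu(C), var(C);
  if (training) {
    // accumulate channel sums in double to keep the statistics stable
    arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
    for (int s = 0; s < B; ++s)
      for (int c = 0; c < C; ++c) {
        const float* xc = x.slice(s).colptr(c);
        double a1 = 0, a2 = 0;
        for (size_t q = 0; q < HW; ++q) { a1 += xc[q]; a2 += (double)xc[q] * xc[q]; }
        s1(c) += a1; s2(c) += a2;
      }
    for (int c = 0; c < C; ++c) {
      const double mc = s1(c) / m;
      double vc = s2(c) / m - mc * mc;
      if (vc < 0) vc = 0;
      mu(c) = (float)mc; var(c) = (float)vc;
    }
    p.rmean = F_BN_MOM * p.rmean + (1 - F_BN_MOM) * mu;
    p.rvar = F_BN_MOM * p.rvar +
             (1 - F_BN_MOM) * var * (float)(m / std::max(m - 1, 1.0));
  } else {
    mu = p.rmean; var = p.rvar;
  }
  FV ivstd = 1.0f / arma::sqrt(var + F_BN_EPS);
  FC y(arma::size(x));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const float* xc = x.slice(s).colptr(c);
      float* yc = y.slice(s).colptr(c);
      const float a = p.gamma(c) * ivstd(c);
      const float d = p.beta(c) - a * mu(c);
      for (size_t q = 0; q < HW; ++q) {
        const float v = a * xc[q] + d;
        yc[q] = v > 0 ? v : 0;
      }
    }
  cache.x = std::move(x);
  cache.y = y;
  cache.mu = mu; cache.ivstd = ivstd;
  return y;
}

static FC f_bnrelu_bw(FBN& p, const FBNCache& cache, const FC& dy) {
  const int C = cache.x.n_cols, B = cache.x.n_slices;
  const size_t HW = cache.x.n_rows;
  const float m = (float)((double)HW * B);
  arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const float* xc = cache.x.slice(s).colptr(c);
      const float* yc = cache.y.slice(s).colptr(c);
      const float* g = dy.slice(s).colptr(c);
      double a1 = 0, a2 = 0;
      for (size_t q = 0; q < HW; ++q) {
        const float gd = yc[q] <= 0 ? 0.0f : g[q];
        a1 += gd;
        a2 += (double)gd * (xc[q] - cache.mu(c)) * cache.ivstd(c);
      }
      s1(c) += a1; s2(c) += a2;
    }
  FC dx(arma::size(cache.x));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const float* xc = cache.x.slice(s).colptr(c);
      const float* yc = cache.y.slice(s).colptr(c);
      const float* g = dy.slice(s).colptr(c);
      float* d = dx.slice(s).colptr(c);
      const float a = p.gamma(c) * cache.ivstd(c) / m;
      const float t1 = (float)s1(c), t2 = (float)s2(c);
      for (size_t q = 0; q < HW; ++q) {
        const float gd = yc[q] <= 0 ? 0.0f : g[q];
        const float xh = (xc[q] - cache.mu(c)) * cache.ivstd(c);
        d[q] = a * (m * gd - t1 - xh * t2);
      }
    }
  p.dgamma = arma::conv_to<FV>::from(s2);
  p.dbeta = arma::conv_to<FV>::from(s1);
  return dx;
}

// ---- max pooling ------------------------------------------------------------

static FC f_maxpool3_fw(const FC& x, UC& idx) {
  const int H = 64, Wd = 64;
  const int C = x.n_cols, B = x.n_slices;
  FC y(arma::size(x));
  idx.set_size(x.n_rows, C, B);
  std::vector<float> m1((size_t)H * Wd);
  std::vector<int> a1((size_t)H * Wd);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const float* xc = x.slice(s).colptr(c);
      float* yc = y.slice(s).colptr(c);
      arma::uword* ic = idx.slice(s).colptr(c);
      for (int j = 0; j < Wd; ++j) {
        const float* s0 = xc + (size_t)j * H;
        float* d = m1.data() + (size_t)j * H;
        int* a = a1.data() + (size_t)j * H;
        for (int i = 0; i < H; ++i) {
          float best = s0[i]; int bi = i;
          if (i > 0 && s0[i - 1] > best) { best = s0[i - 1]; bi = i - 1; }
          if (i + 1 < H && s0[i + 1] > best) { best = s0[i + 1]; bi = i + 1; }
          d[i] = best; a[i] = bi;
        }
      }
      for (int j = 0; j < Wd; ++j) {
        float* yj = yc + (size_t)j * H;
        arma::uword* ij = ic + (size_t)j * H;
        for (int i = 0; i < H; ++i) {
          float best = m1[(size_t)j * H + i]; int bj = j;
          if (j > 0 && m1[(size_t)(j - 1) * H + i] > best) {
            best = m1[(size_t)(j - 1) * H + i]; bj = j - 1;
          }
          if (j + 1 < Wd && m1[(size_t)(j + 1) * H + i] > best) {
            best = m1[(size_t)(j + 1) * H + i]; bj = j + 1;
          }
          yj[i] = best;
          ij[i] = (size_t)bj * H + a1[(size_t)bj * H + i];
        }
      }
    }
  return y;
}

static FC f_maxpool3_bw(const FC& dy, const UC& idx) {
  FC dx(arma::size(dy), arma::fill::zeros);
  const int C = dy.n_cols, B = dy.n_slices;
  const size_t HW = dy.n_rows;
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const float* g = dy.slice(s).colptr(c);
      const arma::uword* ic = idx.slice(s).colptr(c);
      float* d = dx.slice(s).colptr(c);
      for (size_t p = 0; p < HW; ++p) d[ic[p]] += g[p];
    }
  return dx;
}

// ---- composite blocks -------------------------------------------------------

struct FFEB { FConv c1, c2; FBN n1, n2; };
struct FFEBCache { FBNCache b1, b2; };

static FC f_feb_fw(FFEB& p, const FC& x, bool training, FFEBCache& cache) {
  FC c1 = f_conv_fw(p.c1, x);
  FC y1 = f_bnrelu_fw(p.n1, std::move(c1), training, cache.b1);
  FC c2 = f_conv_fw(p.c2, y1);
  return f_bnrelu_fw(p.n2, std::move(c2), training, cache.b2);
}

static FC f_feb_bw(FFEB& p, const FC& x, const FFEBCache& cache, const FC& dy) {
  FC d2 = f_bnrelu_bw(p.n2, cache.b2, dy);
  FC d1 = f_conv_bw(p.c2, cache.b1.y, d2);
  FC d0 = f_bnrelu_bw(p.n1, cache.b1, d1);
  return f_conv_bw(p.c1, x, d0);
}

struct FFusion { FFEB f1, f3, f5; FConv pc; };
struct FFusionCache {
  FC x; FFEBCache f1, f3, f5;
  UC mpIdx; FC mpY, prY;
  int nb[4];
};

static FC f_fusion_fw(FFusion& p, FC&& xin, bool training, FFusionCache& cache) {
  cache.x = std::move(xin);
  FC y1 = f_feb_fw(p.f1, cache.x, training, cache.f1);
  FC y3 = f_feb_fw(p.f3, cache.x, training, cache.f3);
  FC y5 = f_feb_fw(p.f5, cache.x, training, cache.f5);
  cache.mpY = f_maxpool3_fw(cache.x, cache.mpIdx);
  FC pc = f_conv_fw(p.pc, cache.mpY);
  cache.prY = arma::clamp(pc, 0.0f, std::numeric_limits<float>::infinity());
  const int B = cache.x.n_slices;
  cache.nb[0] = y1.n_cols; cache.nb[1] = y3.n_cols;
  cache.nb[2] = y5.n_cols; cache.nb[3] = cache.prY.n_cols;
  FC y(cache.x.n_rows, cache.nb[0] + cache.nb[1] + cache.nb[2] + cache.nb[3], B);
  for (int s = 0; s < B; ++s) {
    int off = 0;
    y.slice(s).cols(off, off + cache.nb[0] - 1) = y1.slice(s); off += cache.nb[0];
    y.slice(s).cols(off, off + cache.nb[1] - 1) = y3.slice(s); off += cache.nb[1];
    y.slice(s).cols(off, off + cache.nb[2] - 1) = y5.slice(s); off += cache.nb[2];
    y.slice(s).cols(off, off + cache.nb[3] - 1) = cache.prY.slice(s);
  }
  return y;
}

static FC f_fusion_bw(FFusion& p, const FFusionCache& cache, const FC& dy) {
  const int B = cache.x.n_slices;
  const size_t HW = cache.x.n_rows;
  auto part = [&](int block) {
    int off = 0;
    for (int i = 0; i < block; ++i) off += cache.nb[i];
    FC d(HW, cache.nb[block], B);
    for (int s = 0; s < B; ++s)
      d.slice(s) = dy.slice(s).cols(off, off + cache.nb[block] - 1);
    return d;
  };
  FC dx = f_feb_bw(p.f1, cache.x, cache.f1, part(0));
  dx += f_feb_bw(p.f3, cache.x, cache.f3, part(1));
  dx += f_feb_bw(p.f5, cache.x, cache.f5, part(2));
  FC dpr = part(3);
  for (arma::uword q = 0; q < dpr.n_elem; ++q)
    if (cache.prY(q) <= 0) dpr(q) = 0;
  FC dmp = f_conv_bw(p.pc, cache.mpY, dpr);
  dx += f_maxpool3_bw(dmp, cache.mpIdx);
  return dx;
}

struct FDense {
  FM W; FV b;
  FM dW, mW, vW; FV db, mb, vb;
  void initState() {
    dW.zeros(W.n_rows, W.n_cols); mW.zeros(W.n_rows, W.n_cols);
    vW.zeros(W.n_rows, W.n_cols);
    db.zeros(b.n_elem); mb.zeros(b.n_elem); vb.zeros(b.n_elem);
  }
};

struct FCAB {
  FM W1, W2; FV b1, b2;
  FM dW1, dW2, m1, v1, m2, v2; FV db1, db2, mb1, vb1, mb2, vb2;
  void initState() {
    dW1.zeros(W1.n_rows, W1.n_cols); m1.zeros(W1.n_rows, W1.n_cols);
    v1.zeros(W1.n_rows, W1.n_cols);
    dW2.zeros(W2.n_rows, W2.n_cols); m2.zeros(W2.n_rows, W2.n_cols);
    v2.zeros(W2.n_rows, W2.n_cols);
    db1.zeros(b1.n_elem); mb1.zeros(b1.n_elem); vb1.zeros(b1.n_elem);
    db2.zeros(b2.n_elem); mb2.zeros(b2.n_elem); vb2.zeros(b2.n_elem);
  }
};

struct FCABCache { FC x; FM z, a1, w; arma::umat maxIdx; };

static FC f_cab_fw(FCAB& p, FC&& xin, FCABCache& cache) {
  const int C = xin.n_cols, B = xin.n_slices;
  const size_t HW = xin.n_rows;
  FM zavg(C, B), zmax(C, B);
  arma::umat idx(C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      zavg(c, s) = arma::mean(xin.slice(s).col(c));
      arma::uword bi;
      zmax(c, s) = xin.slice(s).col(c).max(bi);
      idx(c, s) = bi;
    }
  FM z = zavg + zmax;
  FM h1 = p.W1.t() * z; h1.each_col() += p.b1;
  FM a1 = arma::clamp(h1, 0.0f, std::numeric_limits<float>::infinity());
  FM u = p.W2.t() * a1; u.each_col() += p.b2;
  FM w = 1.0f / (1.0f + arma::exp(-u));
  FC y(arma::size(xin));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      y.slice(s).col(c) = w(c, s) * xin.slice(s).col(c);
  cache.x = std::move(xin); cache.z = z; cache.a1 = a1; cache.w = w;
  cache.maxIdx = idx;
  return y;
}

static FC f_cab_bw(FCAB& p, const FCABCache& cache, const FC& dy) {
  const int C = cache.x.n_cols, B = cache.x.n_slices;
  const size_t HW = cache.x.n_rows;
  FM dw(C, B);
  FC dx(arma::size(cache.x));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      dw(c, s) = arma::dot(dy.slice(s).col(c), cache.x.slice(s).col(c));
      dx.slice(s).col(c) = cache.w(c, s) * dy.slice(s).col(c);
    }
  FM du = dw % cache.w % (1.0f - cache.w);
  p.dW2 = cache.a1 * du.t();
  p.db2 = arma::sum(du, 1);
  FM da1 = p.W2 * du;
  FM dh1 = da1;
  for (arma::uword q = 0; q < dh1.n_elem; ++q)
    if (cache.a1(q) <= 0) dh1(q) = 0;
  p.dW1 = cache.z * dh1.t();
  p.db1 = arma::sum(dh1, 1);
  FM dz = p.W1 * dh1;
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      dx.slice(s).col(c) += dz(c, s) / (float)HW;
      dx.slice(s)(cache.maxIdx(c, s), c) += dz(c, s);
    }
  return dx;
}

// ---- network ----------------------------------------------------------------

struct FNet {
  bool hasFEB, hasFusion, hasCAB;
  int nFusion;
  FDense fc1, fc2;
  FFEB feb0;
  std::vector<FFusion> fus;
  FCAB cab;
  FConv out;
};

static FM getFM(const Rcpp::List& l, const char* nm) {
  return arma::conv_to<FM>::from(Rcpp::as<arma::mat>(l[nm]));
}
static FV getFV(const Rcpp::List& l, const char* nm) {
  return arma::conv_to<FV>::from(Rcpp::as<arma::vec>(l[nm]));
}
static FConv getFConv(const Rcpp::List& l) {
  FConv p; p.W = getFM(l, "W"); p.b = getFV(l, "b");
  p.k = Rcpp::as<int>(l["k"]); p.initState(); return p;
}
static FBN getFBN(const Rcpp::List& l) {
  FBN p; p.gamma = getFV(l, "gamma"); p.beta = getFV(l, "beta");
  p.rmean = getFV(l, "rmean"); p.rvar = getFV(l, "rvar");
  p.initState(); return p;
}
static FFEB getFFEB(const Rcpp::List& l) {
  FFEB p; p.c1 = getFConv(l["conv1"]); p.n1 = getFBN(l["bn1"]);
  p.c2 = getFConv(l["conv2"]); p.n2 = getFBN(l["bn2"]); return p;
}
static FFusion getFFusion(const Rcpp::List& l) {
  FFusion p; p.f1 = getFFEB(l["feb1"]); p.f3 = getFFEB(l["feb3"]);
  p.f5 = getFFEB(l["feb5"]); p.pc = getFConv(l["poolconv"]); return p;
}

static FNet parseNet(const Rcpp::List& params, const std::string& variant,
                     int nFusion) {
  FNet n;
  n.hasFEB = variant != "no_feb";
  n.hasFusion = variant != "feb_only";
  n.hasCAB = variant == "full" || variant == "no_feb";
  n.nFusion = n.hasFusion ? nFusion : 0;
  Rcpp::List fc1 = params["fc1"], fc2 = params["fc2"];
  n.fc1.W = getFM(fc1, "W"); n.fc1.b = getFV(fc1, "b"); n.fc1.initState();
  n.fc2.W = getFM(fc2, "W"); n.fc2.b = getFV(fc2, "b"); n.fc2.initState();
  if (n.hasFEB) n.feb0 = getFFEB(params["feb0"]);
  for (int i = 0; i < n.nFusion; ++i)
    n.fus.push_back(getFFusion(params["fusion" + std::to_string(i + 1)]));
  if (n.hasCAB) {
    Rcpp::List c = params["cab"];
    n.cab.W1 = getFM(c, "W1"); n.cab.b1 = getFV(c, "b1");
    n.cab.W2 = getFM(c, "W2"); n.cab.b2 = getFV(c, "b2");
    n.cab.initState();
  }
  n.out = getFConv(params["out"]);
  return n;
}

static SEXP putM(const FM& m) { return Rcpp::wrap(arma::conv_to<arma::mat>::from(m)); }
static SEXP putV(const FV& v) { return Rcpp::wrap(arma::conv_to<arma::vec>::from(v)); }
static Rcpp::List putConv(const FConv& p) {
  return Rcpp::List::create(Rcpp::Named("W") = putM(p.W),
                            Rcpp::Named("b") = putV(p.b),
                            Rcpp::Named("k") = p.k);
}
static Rcpp::List putBN(const FBN& p) {
  return Rcpp::List::create(Rcpp::Named("gamma") = putV(p.gamma),
                            Rcpp::Named("beta") = putV(p.beta),
                            Rcpp::Named("rmean") = putV(p.rmean),
                            Rcpp::Named("rvar") = putV(p.rvar));
}
static Rcpp::List putFEB(const FFEB& p) {
  return Rcpp::List::create(Rcpp::Named("conv1") = putConv(p.c1),
                            Rcpp::Named("bn1") = putBN(p.n1),
                            Rcpp::Named("conv2") = putConv(p.c2),
                            Rcpp::Named("bn2") = putBN(p.n2));
}
static Rcpp::List putFusion(const FFusion& p) {
  return Rcpp::List::create(Rcpp::Named("feb1") = putFEB(p.f1),
                            Rcpp::Named("feb3") = putFEB(p.f3),
                            Rcpp::Named("feb5") = putFEB(p.f5),
                            Rcpp::Named("poolconv") = putConv(p.pc));
}
static Rcpp::List putNet(const FNet& n) {
  Rcpp::List out;
  out["fc1"] = Rcpp::List::create(Rcpp::Named("W") = putM(n.fc1.W),
                                  Rcpp::Named("b") = putV(n.fc1.b));
  out["fc2"] = Rcpp::List::create(Rcpp::Named("W") = putM(n.fc2.W),
                                  Rcpp::Named("b") = putV(n.fc2.b));
  if (n.hasFEB) out["feb0"] = putFEB(n.feb0);
  for (int i = 0; i < n.nFusion; ++i)
    out["fusion" + std::to_string(i + 1)] = putFusion(n.fus[i]);
  if (n.hasCAB)
    out["cab"] = Rcpp::List::create(Rcpp::Named("W1") = putM(n.cab.W1),
                                    Rcpp::Named("b1") = putV(n.cab.b1),
                                    Rcpp::Named("W2") = putM(n.cab.W2),
                                    Rcpp::Named("b2") = putV(n.cab.b2));
  out["out"] = putConv(n.out);
  return out;
}

struct FNetCache {
  FM h1, h2;
  FC feb0In;
  FFEBCache feb0;
  std::vector<FFusionCache> fus;
  FCABCache cab;
  FC outIn;
};

// forward; when dOut != NULL also backward (accumulating grads into net)
static FC net_fw(FNet& net, const FM& X, bool training, FNetCache& cache) {
  const int B = X.n_cols;
  cache.h1 = arma::tanh(net.fc1.W.t() * X + arma::repmat(net.fc1.b, 1, B));
  cache.h2 = arma::tanh(net.fc2.W.t() * cache.h1 + arma::repmat(net.fc2.b, 1, B));
  FC x(4096, 1, B);
  for (int s = 0; s < B; ++s) x.slice(s).col(0) = cache.h2.col(s);
  if (net.hasFEB) {
    cache.feb0In = x;
    x = f_feb_fw(net.feb0, cache.feb0In, training, cache.feb0);
  }
  cache.fus.resize(net.nFusion);
  for (int i = 0; i < net.nFusion; ++i)
    x = f_fusion_fw(net.fus[i], std::move(x), training, cache.fus[i]);
  if (net.hasCAB) x = f_cab_fw(net.cab, std::move(x), cache.cab);
  cache.outIn = x;
  return f_conv_fw(net.out, cache.outIn);
}

static void net_bw(FNet& net, const FM& X, FNetCache& cache, const FC& dOut) {
  FC dx = f_conv_bw(net.out, cache.outIn, dOut);
  if (net.hasCAB) dx = f_cab_bw(net.cab, cache.cab, dx);
  for (int i = net.nFusion - 1; i >= 0; --i)
    dx = f_fusion_bw(net.fus[i], cache.fus[i], dx);
  if (net.hasFEB) dx = f_feb_bw(net.feb0, cache.feb0In, cache.feb0, dx);
  const int B = X.n_cols;
  FM dflat(4096, B);
  for (int s = 0; s < B; ++s) dflat.col(s) = dx.slice(s).col(0);
  dflat %= (1.0f - arma::square(cache.h2));
  net.fc2.dW = cache.h1 * dflat.t();
  net.fc2.db = arma::sum(dflat, 1);
  FM dh1 = net.fc2.W * dflat;
  dh1 %= (1.0f - arma::square(cache.h1));
  net.fc1.dW = X * dh1.t();
  net.fc1.db = arma::sum(dh1, 1);
}

// ---- Adam -------------------------------------------------------------------

static void adamM(FM& p, const FM& g, FM& m, FM& v, float corr, float b1,
                  float b2, float eps) {
  const arma::uword n = p.n_elem;
  float* pp = p.memptr(); const float* gg = g.memptr();
  float* mm = m.memptr(); float* vv = v.memptr();
  for (arma::uword i = 0; i < n; ++i) {
    mm[i] = b1 * mm[i] + (1 - b1) * gg[i];
    vv[i] = b2 * vv[i] + (1 - b2) * gg[i] * gg[i];
    pp[i] -= corr * mm[i] / (std::sqrt(vv[i]) + eps);
  }
}
static void adamV(FV& p, const FV& g, FV& m, FV& v, float corr, float b1,
                  float b2, float eps) {
  const arma::uword n = p.n_elem;
  float* pp = p.memptr(); const float* gg = g.memptr();
  float* mm = m.memptr(); float* vv = v.memptr();
  for (arma::uword i = 0; i < n; ++i) {
    mm[i] = b1 * mm[i] + (1 - b1) * gg[i];
    vv[i] = b2 * vv[i] + (1 - b2) * gg[i] * gg[i];
    pp[i] -= corr * mm[i] / (std::sqrt(vv[i]) + eps);
  }
}
static void adamConv(FConv& p, float corr, float b1, float b2, float eps) {
  adamM(p.W, p.dW, p.mW, p.vW, corr, b1, b2, eps);
  adamV(p.b, p.db, p.mb, p.vb, corr, b1, b2, eps);
}
static void adamBN(FBN& p, float corr, float b1, float b2, float eps) {
  adamV(p.gamma, p.dgamma, p.mg, p.vg, corr, b1, b2, eps);
  adamV(p.beta, p.dbeta, p.mbe, p.vbe, corr, b1, b2, eps);
}
static void adamFEB(FFEB& p, float corr, float b1, float b2, float eps) {
  adamConv(p.c1, corr, b1, b2, eps); adamBN(p.n1, corr, b1, b2, eps);
  adamConv(p.c2, corr, b1, b2, eps); adamBN(p.n2, corr, b1, b2, eps);
}
static void adamNet(FNet& n, float corr, float b1, float b2, float eps) {
  adamM(n.fc1.W, n.fc1.dW, n.fc1.mW, n.fc1.vW, corr, b1, b2, eps);
  adamV(n.fc1.b, n.fc1.db, n.fc1.mb, n.fc1.vb, corr, b1, b2, eps);
  adamM(n.fc2.W, n.fc2.dW, n.fc2.mW, n.fc2.vW, corr, b1, b2, eps);
  adamV(n.fc2.b, n.fc2.db, n.fc2.mb, n.fc2.vb, corr, b1, b2, eps);
  if (n.hasFEB) adamFEB(n.feb0, corr, b1, b2, eps);
  for (int i = 0; i < n.nFusion; ++i) {
    adamFEB(n.fus[i].f1, corr, b1, b2, eps);
    adamFEB(n.fus[i].f3, corr, b1, b2, eps);
    adamFEB(n.fus[i].f5, corr, b1, b2, eps);
    adamConv(n.fus[i].pc, corr, b1, b2, eps);
  }
  if (n.hasCAB) {
    adamM(n.cab.W1, n.cab.dW1, n.cab.m1, n.cab.v1, corr, b1, b2, eps);
    adamV(n.cab.b1, n.cab.db1, n.cab.mb1, n.cab.vb1, corr, b1, b2, eps);
    adamM(n.cab.W2, n.cab.dW2, n.cab.m2, n.cab.v2, corr, b1, b2, eps);
    adamV(n.cab.b2, n.cab.db2, n.cab.mb2, n.cab.vb2, corr, b1, b2, eps);
  }
  adamConv(n.out, corr, b1, b2, eps);
}

static double evalSplit(FNet& net, const FM& X, const FC& Y,
                        const arma::vec& lw, int batchSize) {
  const int n = X.n_cols;
  double tot = 0;
  FNetCache cache;
  for (int s0 = 0; s0 < n; s0 += batchSize) {
    const int b1 = std::min(s0 + batchSize, n) - 1;
    FM Xb = X.cols(s0, b1);
    FC y = net_fw(net, Xb, false, cache);
    const int B = Xb.n_cols;
    double l1 = 0, l2 = 0;
    for (int s = 0; s < B; ++s) {
      l1 += arma::accu(arma::square(y.slice(s).col(0) - Y.slice(s0 + s).col(0)));
      l2 += arma::accu(arma::square(y.slice(s).col(1) - Y.slice(s0 + s).col(1)));
    }
    tot += (lw(0) * l1 + lw(1) * l2) / 4096.0;
  }
  return tot / n;
}

// Full minibatch-Adam training loop.  perms holds one 1-based permutation of
// the training indices per epoch (from R's RNG, so runs are seed-exact).
// [[Rcpp::export(name = ".cafnet_train")]]
Rcpp::List cafnet_train(const Rcpp::List& params, const arma::mat& X,
                        const arma::cube& Y, const arma::mat& Xval,
                        const arma::cube& Yval, const arma::vec& lossWeights,
                        const std::string& variant, int nFusion,
                        const arma::imat& perms, int batchSize, double lr,
                        double beta1, double beta2,
                        const arma::ivec& snapshotEpochs, bool verbose) {
  FNet net = parseNet(params, variant, nFusion);
  const int nTr = X.n_cols, epochs = perms.n_cols;
  FM Xf = arma::conv_to<FM>::from(X);
  // per-sample target slices (4096 x 2 each)
  FC Yf = arma::conv_to<FC>::from(Y);
  FM Xvf; FC Yvf;
  const bool hasVal = Xval.n_cols > 0;
  if (hasVal) { Xvf = arma::conv_to<FM>::from(Xval); Yvf = arma::conv_to<FC>::from(Yval); }
  arma::vec trainLoss(epochs), valLoss(epochs, arma::fill::value(NA_REAL));
  Rcpp::List snapshots;
  FNetCache cache;
  long t = 0;
  const float eps = 1e-7f;
  for (int ep = 0; ep < epochs; ++ep) {
    double epLoss = 0;
    for (int s0 = 0; s0 < nTr; s0 += batchSize) {
      const int B = std::min(s0 + batchSize, nTr) - s0;
      FM Xb(480, B);
      FC Yb(4096, 2, B);
      for (int s = 0; s < B; ++s) {
        const int src = perms(s0 + s, ep) - 1;
        Xb.col(s) = Xf.col(src);
        Yb.slice(s) = Yf.slice(src);
      }
      FC y = net_fw(net, Xb, true, cache);
      const double n = 4096.0 * B;
      double l1 = 0, l2 = 0;
      FC dOut(arma::size(y));
      for (int s = 0; s < B; ++s) {
        FV d1 = y.slice(s).col(0) - Yb.slice(s).col(0);
        FV d2 = y.slice(s).col(1) - Yb.slice(s).col(1);
        l1 += arma::dot(d1, d1); l2 += arma::dot(d2, d2);
        dOut.slice(s).col(0) = (float)(2.0 * lossWeights(0) / n) * d1;
        dOut.slice(s).col(1) = (float)(2.0 * lossWeights(1) / n) * d2;
      }
      epLoss += (lossWeights(0) * l1 + lossWeights(1) * l2) / 4096.0;
      net_bw(net, Xb, cache, dOut);
      ++t;
      const float corr = (float)(lr * std::sqrt(1 - std::pow(beta2, (double)t)) /
                                 (1 - std::pow(beta1, (double)t)));
      adamNet(net, corr, (float)beta1, (float)beta2, eps);
      Rcpp::checkUserInterrupt();
    }
    trainLoss(ep) = epLoss / nTr;
    if (hasVal) valLoss(ep) = evalSplit(net, Xvf, Yvf, lossWeights, batchSize);
    for (arma::uword i = 0; i < snapshotEpochs.n_elem; ++i)
      if (snapshotEpochs(i) == ep + 1)
        snapshots[std::to_string(ep + 1)] = putNet(net);
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << ": train " << trainLoss(ep)
                  << (hasVal ? " val " + std::to_string(valLoss(ep)) : "")
                  << std::endl;
  }
  return Rcpp::List::create(Rcpp::Named("params") = putNet(net),
                            Rcpp::Named("train") = trainLoss,
                            Rcpp::Named("val") = valLoss,
                            Rcpp::Named("snapshots") = snapshots);
}
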