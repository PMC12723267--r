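// BLAS-backed layer kernels for the reconstruction network.
// Feature maps are passed as cubes (H*W pixels, channels, batch), images
// column-major with the first spatial dimension fastest, matching R's
// as.vector() of a 64 x 64 matrix.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

// Gather one channel into the k*k columns of an im2col block (leading dim HW).
// Offset order: t = u + v*k for source pixel (i + u - pad, j + v - pad).
// Interior spans are contiguous memcpy; padded edges are zero-filled.
static void im2col_channel(const double* xc, int H, int W, int k, int pad,
                           double* col) {
  const size_t HW = (size_t)H * W;
  int t = 0;
  for (int v = 0; v < k; ++v) {
    for (int u = 0; u < k; ++u, ++t) {
      double* dst = col + (size_t)t * HW;
      const int du = u - pad, dv = v - pad;
      const int lo = du < 0 ? -du : 0;          // first valid output row
      const int hi = du > 0 ? H - du : H;       // one past last valid row
      for (int j = 0; j < W; ++j) {
        const int sj = j + dv;
        double* d = dst + (size_t)j * H;
        if (sj < 0 || sj >= W) { std::memset(d, 0, sizeof(double) * H); continue; }
        const double* s = xc + (size_t)sj * H + du;
        if (lo > 0) std::memset(d, 0, sizeof(double) * lo);
        std::memcpy(d + lo, s + lo, sizeof(double) * (hi - lo));
        if (hi < H) std::memset(d + hi, 0, sizeof(double) * (H - hi));
      }
    }
  }
}

static void build_col(const double* xslice, int Cin, int H, int W, int k,
                      arma::mat& col) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < Cin; ++c)
    im2col_channel(xslice + (size_t)c * HW, H, W, k, pad,
                   col.colptr((size_t)c * k * k));
}

// Same-padding 2-D convolution. x: (HW, Cin, B); W: (Cin*k*k, Cout).
// k = 1 is a pure channel mix and skips the im2col gather.
// [[Rcpp::export(name = ".conv_fw")]]
arma::cube conv_fw(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                   int H, int Wd, int k) {
  const int B = x.n_slices, Cin = x.n_cols, Cout = W.n_cols;
  const size_t HW = (size_t)H * Wd;
  arma::cube y(HW, Cout, B);
  if (k == 1) {
    for (int s = 0; s < B; ++s) {
      y.slice(s) = x.slice(s) * W;
      y.slice(s).each_row() += b.t();
    }
    return y;
  }
  arma::mat col(HW, (size_t)Cin * k * k);  // reused across the batch
  for (int s = 0; s < B; ++s) {
    build_col(x.slice(s).memptr(), Cin, H, Wd, k, col);
    y.slice(s) = col * W;
    y.slice(s).each_row() += b.t();
  }
  return y;
}

// Backward pass of conv_fw.  The input gradient is itself a same-padding
// convolution of dy with the spatially flipped, channel-transposed kernel,
// so everything stays in im2col + GEMM form (no scatter).
arma::cube conv_bw_impl(const arma::cube& x, const arma::mat& W,
                        const arma::cube& dy, int H, int Wd, int k,
                        arma::mat& dW, arma::vec& db) {
  const int B = x.n_slices, Cin = x.n_cols, Cout = W.n_cols;
  const int kk = k * k;
  const size_t HW = (size_t)H * Wd;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(Cout);
  arma::cube dx(HW, Cin, B);
  if (k == 1) {
    for (int s = 0; s < B; ++s) {
      dW += x.slice(s).t() * dy.slice(s);
      db += arma::sum(dy.slice(s), 0).t();
      dx.slice(s) = dy.slice(s) * W.t();
    }
    return dx;
  }
  // Wr[(cout, t'), cin] = W[(cin, t), cout], t' = k*k-1-t (180-degree flip)
  arma::mat Wr((size_t)Cout * kk, Cin);
  for (int cin = 0; cin < Cin; ++cin)
    for (int t = 0; t < kk; ++t)
      for (int cout = 0; cout < Cout; ++cout)
        Wr((size_t)cout * kk + (kk - 1 - t), cin) = W((size_t)cin * kk + t, cout);
  arma::mat col(HW, (size_t)Cin * kk);
  arma::mat dcol(HW, (size_t)Cout * kk);
  for (int s = 0; s < B; ++s) {
    build_col(x.slice(s).memptr(), Cin, H, Wd, k, col);
    dW += col.t() * dy.slice(s);
    db += arma::sum(dy.slice(s), 0).t();
    build_col(dy.slice(s).memptr(), Cout, H, Wd, k, dcol);
    dx.slice(s) = dcol * Wr;
  }
  return dx;
}

// [[Rcpp::export(name = ".conv_bw")]]
Rcpp::List conv_bw(const arma::cube& x, const arma::mat& W,
                   const arma::cube& dy, int H, int Wd, int k) {
  arma::mat dW;
  arma::vec db;
  arma::cube dx = conv_bw_impl(x, W, dy, H, Wd, k, dW, db);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 3x3 max pooling, stride 1, same padding, computed separably (row-window
// max, then column-window max) with argmax kept for the backward pass.
arma::cube maxpool3_fw_impl(const arma::cube& x, int H, int Wd,
                            arma::ucube& idx) {
  const int C = x.n_cols, B = x.n_slices;
  arma::cube y(arma::size(x));
  idx.set_size(x.n_rows, C, B);
  std::vector<double> m1((size_t)H * Wd);
  std::vector<int> a1((size_t)H * Wd);
  for (int s = 0; s < B; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(s).colptr(c);
      double* yc = y.slice(s).colptr(c);
      arma::uword* ic = idx.slice(s).colptr(c);
      // pass 1: vertical 3-window max per column
      for (int j = 0; j < Wd; ++j) {
        const double* s0 = xc + (size_t)j * H;
        double* d = m1.data() + (size_t)j * H;
        int* a = a1.data() + (size_t)j * H;
        for (int i = 0; i < H; ++i) {
          double best = s0[i]; int bi = i;
          if (i > 0 && s0[i - 1] > best) { best = s0[i - 1]; bi = i - 1; }
          if (i + 1 < H && s0[i + 1] > best) { best = s0[i + 1]; bi = i + 1; }
          d[i] = best; a[i] = bi;
        }
      }
      // pass 2: horizontal 3-window max of the vertical maxima
      for (int j = 0; j < Wd; ++j) {
        double* yj = yc + (size_t)j * H;
        arma::uword* ij = ic + (size_t)j * H;
        for (int i = 0; i < H; ++i) {
          double best = m1[(size_t)j * H + i]; int bj = j;
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
  }
  return y;
}

// [[Rcpp::export(name = ".maxpool3_fw")]]
Rcpp::List maxpool3_fw(const arma::cube& x, int H, int Wd) {
  arma::ucube idx;
  arma::cube y = maxpool3_fw_impl(x, H, Wd, idx);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool3_bw")]]
arma::cube maxpool3_bw(const arma::cube& dy, const arma::ucube& idx) {
  arma::cube dx(arma::size(dy), arma::fill::zeros);
  const int C = dy.n_cols, B = dy.n_slices;
  const size_t HW = dy.n_rows;
  for (int s = 0; s < B; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* g = dy.slice(s).colptr(c);
      const arma::uword* ic = idx.slice(s).colptr(c);
      double* d = dx.slice(s).colptr(c);
      for (size_t p = 0; p < HW; ++p) d[ic[p]] += g[p];
    }
  }
  return dx;
}

// Batch normalization over (space, batch) per channel, optionally fused with
// ReLU. Returns y plus the per-channel batch statistics needed for backward
// and the updated running statistics.
// [[Rcpp::export(name = ".bn_fw")]]
Rcpp::List bn_fw(const arma::cube& x, const arma::vec& gamma,
                 const arma::vec& beta, const arma::vec& rmean,
                 const arma::vec& rvar, double eps, double momentum,
                 bool training, bool relu) {
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
  } else {
    mu = rmean; var = rvar;
  }
  arma::vec ivstd = 1.0 / arma::sqrt(var + eps);
  arma::cube y(arma::size(x));
  for (int s = 0; s < B; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(s).colptr(c);
      double* yc = y.slice(s).colptr(c);
      const double a = gamma(c) * ivstd(c);
      const double d = beta(c) - a * mu(c);
      if (relu)
        for (size_t p = 0; p < HW; ++p) {
          const double v = a * xc[p] + d;
          yc[p] = v > 0 ? v : 0;
        }
      else
        for (size_t p = 0; p < HW; ++p) yc[p] = a * xc[p] + d;
    }
  }
  arma::vec nrm = rmean, nrv = rvar;
  if (training) {
    nrm = momentum * rmean + (1 - momentum) * mu;
    nrv = momentum * rvar + (1 - momentum) * var * m / std::max(m - 1, 1.0);
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("mu") = mu,
                            Rcpp::Named("ivstd") = ivstd,
                            Rcpp::Named("rmean") = nrm,
                            Rcpp::Named("rvar") = nrv);
}

// Backward of bn_fw (training statistics); y is needed for the ReLU mask.
// [[Rcpp::export(name = ".bn_bw")]]
Rcpp::List bn_bw(const arma::cube& x, const arma::cube& y,
                 const arma::cube& dy, const arma::vec& gamma,
                 const arma::vec& mu, const arma::vec& ivstd, bool relu) {
  const int C = x.n_cols, B = x.n_slices;
  const size_t HW = x.n_rows;
  const double m = (double)HW * B;
  arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(s).colptr(c);
      const double* yc = y.slice(s).colptr(c);
      const double* g = dy.slice(s).colptr(c);
      double a1 = 0, a2 = 0;
      for (size_t p = 0; p < HW; ++p) {
        const double gd = (relu && yc[p] <= 0) ? 0 : g[p];
        a1 += gd;
        a2 += gd * (xc[p] - mu(c)) * ivstd(c);
      }
      s1(c) += a1; s2(c) += a2;
    }
  arma::cube dx(arma::size(x));
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(s).colptr(c);
      const double* yc = y.slice(s).colptr(c);
      const double* g = dy.slice(s).colptr(c);
      double* d = dx.slice(s).colptr(c);
      const double a = gamma(c) * ivstd(c) / m;
      for (size_t p = 0; p < HW; ++p) {
        const double gd = (relu && yc[p] <= 0) ? 0 : g[p];
        const double xh = (xc[p] - mu(c)) * ivstd(c);
        d[p] = a * (m * gd - s1(c) - xh * s2(c));
      }
    }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = s2,
                            Rcpp::Named("dbeta") = s1);
}

// Per-channel, per-sample spatial max and argmax (global max pooling).
// [[Rcpp::export(name = ".gmp_fw")]]
Rcpp::List gmp_fw(const arma::cube& x) {
  const int C = x.n_cols, B = x.n_slices;
  arma::mat z(C, B);
  arma::umat idx(C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      arma::uword bi;
      z(c, s) = x.slice(s).col(c).max(bi);
      idx(c, s) = bi;
    }
  return Rcpp::List::create(Rcpp::Named("z") = z, Rcpp::Named("idx") = idx);
}
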