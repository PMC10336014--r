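// Minimal seeded 2-D conv-net primitives (double precision, batch-last layout).
//
// All image batches are R arrays with dim (H, W, C, N), column-major, so the
// fastest index is the image row.  Convolutions are computed per sample as a
// GEMM over an im2col patch matrix (rows ordered p + k*q + k*k*c).  Layers are
// deliberately limited to what the slice-prediction U-Net needs: same-padding
// odd-kernel convolution, 2x2 stride-2 transposed convolution, and 2x2 max
// pooling.  Randomness (init, dropout, shuffling) lives on the R side so that
// a single set.seed() pins the whole training run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uvec dim4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D array (H, W, C, N)");
  return arma::uvec({(unsigned)d[0], (unsigned)d[1], (unsigned)d[2], (unsigned)d[3]});
}

// im2col for same-padding odd kernel: out (k*k*C) x (H*W), zero padded.
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& K) {
  const int r = k / 2;
  K.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int q = 0; q < k; ++q) {
      for (int p = 0; p < k; ++p) {
        const int row = p + k * q + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + q - r;
          if (ws < 0 || ws >= W) continue;
          const double* src = xc + (size_t)H * ws;
          double* dst = K.memptr() + (size_t)K.n_rows * ((size_t)H * w) + row;
          const int h0 = std::max(0, r - p), h1 = std::min(H, H + r - p);
          for (int h = h0; h < h1; ++h)
            dst[(size_t)K.n_rows * h] = src[h + p - r];
        }
      }
    }
  }
}

// col2im: accumulate (k*k*C) x (H*W) patch gradients back into (H, W, C).
static void col2im(const arma::mat& K, int H, int W, int C, int k, double* dx) {
  const int r = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int q = 0; q < k; ++q) {
      for (int p = 0; p < k; ++p) {
        const int row = p + k * q + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + q - r;
          if (ws < 0 || ws >= W) continue;
          double* dst = xc + (size_t)H * ws;
          const double* src = K.memptr() + (size_t)K.n_rows * ((size_t)H * w) + row;
          const int h0 = std::max(0, r - p), h1 = std::min(H, H + r - p);
          for (int h = h0; h < h1; ++h)
            dst[h + p - r] += src[(size_t)K.n_rows * h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  arma::uvec dx = dim4(x), dw = dim4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], O = dw[3];
  if ((int)dw[1] != k || (int)dw[2] != C) stop("kernel/channel mismatch");
  NumericVector y((size_t)H * W * O * N);
  y.attr("dim") = IntegerVector::create(H, W, O, N);
  arma::mat W2(const_cast<double*>(w.begin()), (size_t)k * k * C, O, false, true);
  arma::mat K((size_t)k * k * C, (size_t)H * W);
  arma::colvec bv(const_cast<double*>(b.begin()), O, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, K);
    arma::mat Y(y.begin() + (size_t)H * W * O * n, (size_t)H * W, O, false, true);
    Y = K.t() * W2;
    Y.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  arma::uvec dx_ = dim4(x), dw_ = dim4(w);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], O = dw_[3];
  NumericVector dx((size_t)H * W * C * N), dw((size_t)k * k * C * O), db(O);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dw.attr("dim") = IntegerVector::create(k, k, C, O);
  arma::mat W2(const_cast<double*>(w.begin()), (size_t)k * k * C, O, false, true);
  arma::mat dW2(dw.begin(), (size_t)k * k * C, O, false, true);
  arma::colvec dB(db.begin(), O, false, true);
  arma::mat K((size_t)k * k * C, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, K);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * O * n,
                 (size_t)H * W, O, false, true);
    dW2 += K * dY;
    dB += arma::sum(dY, 0).t();
    arma::mat dK = W2 * dY.t();
    col2im(dK, H, W, C, k, dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 transposed convolution: output (2H, 2W, O, N).
// y(2i+p, 2j+q, o) = b_o + sum_c w(p, q, c, o) x(i, j, c); taps never overlap.
// [[Rcpp::export(name = ".tconv2_fw")]]
NumericVector tconv2_fw(NumericVector x, NumericVector w, NumericVector b) {
  arma::uvec dx = dim4(x), dw = dim4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3], O = dw[3];
  if (dw[0] != 2 || dw[1] != 2 || (int)dw[2] != C) stop("tconv expects 2x2 kernel");
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * O * N);
  y.attr("dim") = IntegerVector::create(H2, W2, O, N);
  // W4: (C) x (4*O) with tap index t = p + 2q
  arma::mat W4(const_cast<double*>(w.begin()), 4, (size_t)C * O, false, true);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* yn = y.begin() + (size_t)H2 * W2 * O * n;
    arma::mat X(const_cast<double*>(xn), (size_t)H * W, C, false, true);
    for (int o = 0; o < O; ++o) {
      arma::mat Wt(const_cast<double*>(w.begin()) + (size_t)4 * C * o, 4, C, false, true);
      arma::mat Y4 = X * Wt.t();  // (HW) x 4
      double* yo = yn + (size_t)H2 * W2 * o;
      for (int q = 0; q < 2; ++q)
        for (int p = 0; p < 2; ++p) {
          const double* col = Y4.colptr(p + 2 * q);
          for (int j = 0; j < W; ++j) {
            double* dst = yo + (size_t)H2 * (2 * j + q) + p;
            const double* src = col + (size_t)H * j;
            for (int i = 0; i < H; ++i) dst[2 * i] = src[i] + b[o];
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv2_bw")]]
List tconv2_bw(NumericVector x, NumericVector w, NumericVector dy) {
  arma::uvec dx_ = dim4(x), dw_ = dim4(w);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3], O = dw_[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector dx((size_t)H * W * C * N), dw(4 * (size_t)C * O), db(O);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dw.attr("dim") = IntegerVector::create(2, 2, C, O);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    const double* dyn = dy.begin() + (size_t)H2 * W2 * O * n;
    arma::mat X(const_cast<double*>(xn), (size_t)H * W, C, false, true);
    arma::mat dX(dx.begin() + (size_t)H * W * C * n, (size_t)H * W, C, false, true);
    for (int o = 0; o < O; ++o) {
      const double* dyo = dyn + (size_t)H2 * W2 * o;
      arma::mat dY4((size_t)H * W, 4);
      for (int q = 0; q < 2; ++q)
        for (int p = 0; p < 2; ++p) {
          double* col = dY4.colptr(p + 2 * q);
          for (int j = 0; j < W; ++j) {
            const double* src = dyo + (size_t)H2 * (2 * j + q) + p;
            double* dst = col + (size_t)H * j;
            for (int i = 0; i < H; ++i) dst[i] = src[2 * i];
          }
        }
      arma::mat Wt(const_cast<double*>(w.begin()) + (size_t)4 * C * o, 4, C, false, true);
      arma::mat dWt(dw.begin() + (size_t)4 * C * o, 4, C, false, true);
      dWt += dY4.t() * X;
      dX += dY4 * Wt;
      db[o] += arma::accu(dY4);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 max pooling; returns pooled values and flat argmax indices.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  arma::uvec d = dim4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t out = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const size_t base = (size_t)2 * i + (size_t)H * 2 * j;
          size_t best = base;
          double bv = xc[base];
          const size_t cand[3] = {base + 1, base + H, base + H + 1};
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
          y[out] = bv;
          idx[out] = (int)(best + (size_t)H * W * (c + (size_t)C * n));
          ++out;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  size_t len = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  for (R_xlen_t t = 0; t < dy.size(); ++t) dx[idx[t]] += dy[t];
  return dx;
}
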