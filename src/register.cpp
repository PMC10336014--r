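// 2-D B-spline free-form deformable registration and image resampling.
//
// The registration follows the parameterization used for the MDISP metric:
// local (ANTs-style) neighborhood correlation with radius 2 as similarity,
// a two-level pyramid (smooth sigma 0.25 + half resolution, then full
// resolution), a 4x4 deformation mesh doubled to 8x8, and plain gradient
// ascent on the correlation energy with a step normalized each iteration to
// a maximum displacement in physical units.  Convergence is declared when
// the improvement of the windowed mean metric falls below a threshold.
//
// Images are H x W arma::mat (column-major R matrices); pixel (i, j) with
// 0-based continuous coordinates.  Displacement fields are in pixel units
// internally; the R wrapper converts to mm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample with border clamp.
static double sample_bilinear(const arma::mat& img, double i, double j) {
  const int H = img.n_rows, W = img.n_cols;
  i = clampd(i, 0.0, H - 1.0);
  j = clampd(j, 0.0, W - 1.0);
  const int i0 = std::min((int)std::floor(i), H - 2 >= 0 ? H - 2 : 0);
  const int j0 = std::min((int)std::floor(j), W - 2 >= 0 ? W - 2 : 0);
  const double di = i - i0, dj = j - j0;
  return img(i0, j0) * (1 - di) * (1 - dj) + img(i0 + 1, j0) * di * (1 - dj) +
         img(i0, j0 + 1) * (1 - di) * dj + img(i0 + 1, j0 + 1) * di * dj;
}

// [[Rcpp::export(name = ".warp_field")]]
arma::mat warp_field(const arma::mat& img, const arma::mat& ux, const arma::mat& uy) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = sample_bilinear(img, i + ux(i, j), j + uy(i, j));
  return out;
}

// Rigid in-plane augmentation warp: rotation (deg) about the center plus a
// translation (pixels), sampled backward with border clamp.
// [[Rcpp::export(name = ".warp_rigid")]]
arma::mat warp_rigid(const arma::mat& img, double angle_deg, double ti, double tj) {
  const int H = img.n_rows, W = img.n_cols;
  const double th = angle_deg * M_PI / 180.0, c = std::cos(th), s = std::sin(th);
  const double ci = (H - 1) / 2.0, cj = (W - 1) / 2.0;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double yi = i - ci - ti, yj = j - cj - tj;   // undo translation
      const double si = c * yi + s * yj + ci;            // inverse rotation
      const double sj = -s * yi + c * yj + cj;
      out(i, j) = sample_bilinear(img, si, sj);
    }
  return out;
}

// Separable Gaussian smoothing, reflected borders.
// [[Rcpp::export(name = ".gauss_smooth")]]
arma::mat gauss_smooth(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * r + 1);
  for (int t = -r; t <= r; ++t) k(t + r) = std::exp(-0.5 * t * t / (sigma * sigma));
  k /= arma::accu(k);
  const int H = img.n_rows, W = img.n_cols;
  arma::mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        if (ii >= H) ii = 2 * H - ii - 1;
        acc += k(t + r) * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj - 1;
        if (jj >= W) jj = 2 * W - jj - 1;
        acc += k(t + r) * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

static arma::mat downsample_half(const arma::mat& img) {
  const int H = img.n_rows / 2, W = img.n_cols / 2;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = 0.25 * (img(2 * i, 2 * j) + img(2 * i + 1, 2 * j) +
                          img(2 * i, 2 * j + 1) + img(2 * i + 1, 2 * j + 1));
  return out;
}

// Cubic B-spline basis, s in [0, 1), four support weights.
static inline void bspline_w(double s, double* w) {
  const double s2 = s * s, s3 = s2 * s;
  w[0] = (1 - 3 * s + 3 * s2 - s3) / 6.0;
  w[1] = (4 - 6 * s2 + 3 * s3) / 6.0;
  w[2] = (1 + 3 * s + 3 * s2 - 3 * s3) / 6.0;
  w[3] = s3 / 6.0;
}

// Evaluate a cubic B-spline field on the pixel grid.  coef is
// (mesh+3) x (mesh+3); the mesh spans the image domain with `mesh` cells.
static arma::mat bspline_eval(const arma::mat& coef, int H, int W, int mesh) {
  arma::mat out(H, W, arma::fill::zeros);
  double wi[4], wj[4];
  for (int j = 0; j < W; ++j) {
    double tj = (W > 1) ? (double)j / (W - 1) * mesh : 0.0;
    int cj = std::min((int)std::floor(tj), mesh - 1);
    bspline_w(tj - cj, wj);
    for (int i = 0; i < H; ++i) {
      double ti = (H > 1) ? (double)i / (H - 1) * mesh : 0.0;
      int ci = std::min((int)std::floor(ti), mesh - 1);
      bspline_w(ti - ci, wi);
      double acc = 0;
      for (int b = 0; b < 4; ++b)
        for (int a = 0; a < 4; ++a)
          acc += wi[a] * wj[b] * coef(ci + a, cj + b);
      out(i, j) = acc;
    }
  }
  return out;
}

// Project a per-pixel force field onto the B-spline control grid.
static arma::mat bspline_project(const arma::mat& force, int mesh) {
  const int H = force.n_rows, W = force.n_cols;
  arma::mat g(mesh + 3, mesh + 3, arma::fill::zeros);
  double wi[4], wj[4];
  for (int j = 0; j < W; ++j) {
    double tj = (W > 1) ? (double)j / (W - 1) * mesh : 0.0;
    int cj = std::min((int)std::floor(tj), mesh - 1);
    bspline_w(tj - cj, wj);
    for (int i = 0; i < H; ++i) {
      double ti = (H > 1) ? (double)i / (H - 1) * mesh : 0.0;
      int ci = std::min((int)std::floor(ti), mesh - 1);
      bspline_w(ti - ci, wi);
      const double f = force(i, j);
      if (f == 0) continue;
      for (int b = 0; b < 4; ++b)
        for (int a = 0; a < 4; ++a)
          g(ci + a, cj + b) += wi[a] * wj[b] * f;
    }
  }
  return g;
}

// Windowed sums via truncated (in-image) box windows of radius r.
static void box_sums(const arma::mat& x, int r, arma::mat& out, arma::mat& cnt) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat col(H, W);
  arma::mat ccol(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0; int n = 0;
      const int i0 = std::max(0, i - r), i1 = std::min(H - 1, i + r);
      for (int t = i0; t <= i1; ++t) { acc += x(t, j); ++n; }
      col(i, j) = acc; ccol(i, j) = n;
    }
  out.set_size(H, W); cnt.set_size(H, W);
  for (int j = 0; j < W; ++j) {
    const int j0 = std::max(0, j - r), j1 = std::min(W - 1, j + r);
    for (int i = 0; i < H; ++i) {
      double acc = 0, n = 0;
      for (int t = j0; t <= j1; ++t) { acc += col(i, t); n += ccol(i, t); }
      out(i, j) = acc; cnt(i, j) = n;
    }
  }
}

// Local neighborhood correlation energy CC^2 = A^2/(B*C) and its derivative
// with respect to the moving (warped) image at the window center.
static double ncc_value_grad(const arma::mat& F, const arma::mat& M, int r,
                             arma::mat& dM) {
  const int H = F.n_rows, W = F.n_cols;
  arma::mat SF, SM, SFF, SMM, SFM, cnt, dummy;
  box_sums(F, r, SF, cnt);
  box_sums(M, r, SM, dummy);
  box_sums(F % F, r, SFF, dummy);
  box_sums(M % M, r, SMM, dummy);
  box_sums(F % M, r, SFM, dummy);
  dM.zeros(H, W);
  // windows with (relatively) negligible variance carry no signal and
  // only contribute numerical noise; exclude them
  const double varF = arma::var(arma::vectorise(F));
  const double varM = arma::var(arma::vectorise(M));
  const double tolF = std::max(1e-12, 1e-5 * varF);
  const double tolM = std::max(1e-12, 1e-5 * varM);
  double val = 0;
  long nval = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double n = cnt(i, j);
      const double mf = SF(i, j) / n, mm = SM(i, j) / n;
      const double A = SFM(i, j) - n * mf * mm;
      const double B = SFF(i, j) - n * mf * mf;
      const double C = SMM(i, j) - n * mm * mm;
      if (B < n * tolF || C < n * tolM) continue;
      val += A * A / (B * C);
      ++nval;
      const double If = F(i, j) - mf, Jm = M(i, j) - mm;
      dM(i, j) = 2.0 * A / (B * C) * If - 2.0 * A * A / (B * C * C) * Jm;
    }
  return nval > 0 ? val / nval : 1.0;
}

// Central-difference spatial gradient.
static void grad_img(const arma::mat& x, arma::mat& gi, arma::mat& gj) {
  const int H = x.n_rows, W = x.n_cols;
  gi.set_size(H, W); gj.set_size(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int ip = std::min(i + 1, H - 1), im = std::max(i - 1, 0);
      const int jp = std::min(j + 1, W - 1), jm = std::max(j - 1, 0);
      gi(i, j) = (x(ip, j) - x(im, j)) / (ip - im);
      gj(i, j) = (x(i, jp) - x(i, jm)) / (jp - jm);
    }
}

// One pyramid level of gradient-ascent B-spline registration.  base_ux/uy is
// the (fixed) field carried over from the coarser level, in this level's
// pixel units.  Returns the total field (base + spline) in pixel units.
static void register_level(const arma::mat& fixed, const arma::mat& moving,
                           int mesh, int radius, int iters, double max_step_pix,
                           double conv_min, int conv_win,
                           arma::mat& ux, arma::mat& uy) {
  const int H = fixed.n_rows, W = fixed.n_cols;
  arma::mat cx(mesh + 3, mesh + 3, arma::fill::zeros);
  arma::mat cy(mesh + 3, mesh + 3, arma::fill::zeros);
  arma::mat base_ux = ux, base_uy = uy;
  std::vector<double> vals;
  arma::mat warped(H, W), dM, gi, gj;
  double lr = -1.0;  // estimated once from the first gradient
  for (int it = 0; it < iters; ++it) {
    arma::mat sx = bspline_eval(cx, H, W, mesh), sy = bspline_eval(cy, H, W, mesh);
    ux = base_ux + sx; uy = base_uy + sy;
    warped = warp_field(moving, ux, uy);
    double val = ncc_value_grad(fixed, warped, radius, dM);
    vals.push_back(val);
    if (1.0 - val < 1e-6) break;  // already (near-)perfectly correlated
    // windowed-mean convergence check
    if ((int)vals.size() > conv_win) {
      double m1 = 0, m0 = 0;
      for (int t = 0; t < conv_win; ++t) m1 += vals[vals.size() - 1 - t];
      for (int t = 0; t < conv_win; ++t) m0 += vals[vals.size() - 2 - t];
      if (std::abs(m1 - m0) / conv_win < conv_min) break;
    }
    grad_img(warped, gi, gj);
    arma::mat gx = bspline_project(dM % gi, mesh);
    arma::mat gy = bspline_project(dM % gj, mesh);
    const double gmax = std::max(arma::abs(gx).max(), arma::abs(gy).max());
    if (gmax < 1e-14) break;
    // learning-rate estimation (once): the first step moves control
    // points by at most max_step; later steps scale with the gradient.
    if (lr < 0) lr = max_step_pix / gmax;
    if (lr * gmax < 1e-4 * max_step_pix) break;  // vanished gradient
    cx += lr * gx;
    cy += lr * gy;
  }
  arma::mat sx = bspline_eval(cx, H, W, mesh), sy = bspline_eval(cy, H, W, mesh);
  ux = base_ux + sx; uy = base_uy + sy;
}

static arma::mat upsample2(const arma::mat& x, int H, int W) {
  arma::mat out(H, W);
  const double si = (x.n_rows - 1.0) / std::max(1, H - 1);
  const double sj = (x.n_cols - 1.0) / std::max(1, W - 1);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = sample_bilinear(x, i * si, j * sj);
  return out;
}

// [[Rcpp::export(name = ".register_bspline_cpp")]]
List register_bspline_cpp(const arma::mat& fixed, const arma::mat& moving,
                          int mesh1, int mesh2, int radius, int iters,
                          double sigma1, double max_step_pix,
                          double conv_min, int conv_win) {
  if (!fixed.is_finite() || !moving.is_finite())
    stop("registration requires finite intensities");
  const int H = fixed.n_rows, W = fixed.n_cols;
  // level 1: smooth, half resolution
  arma::mat f1 = downsample_half(gauss_smooth(fixed, sigma1));
  arma::mat m1 = downsample_half(gauss_smooth(moving, sigma1));
  arma::mat ux(f1.n_rows, f1.n_cols, arma::fill::zeros);
  arma::mat uy(f1.n_rows, f1.n_cols, arma::fill::zeros);
  register_level(f1, m1, mesh1, radius, iters, max_step_pix / 2.0,
                 conv_min, conv_win, ux, uy);
  // carry to level 2: displacement doubles in full-resolution pixel units
  arma::mat ux2 = 2.0 * upsample2(ux, H, W);
  arma::mat uy2 = 2.0 * upsample2(uy, H, W);
  register_level(fixed, moving, mesh2, radius, iters, max_step_pix,
                 conv_min, conv_win, ux2, uy2);
  return List::create(_["ui"] = ux2, _["uj"] = uy2);
}
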