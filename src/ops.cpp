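// Low-level numeric kernels: 2-D convolution and bilinear grid sampling,
// forward and backward. Arrays are column-major with dims (H, W, C);
// convolution weights have dims (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Snap coordinates that are within 1e-9 of a pixel center onto it, so that
// (numerically) identity fields reproduce the input bit for bit while the
// gradient path through the sampling locations stays alive.
static inline double snap_coord(double p) {
  double r = std::nearbyint(p);
  return (std::fabs(p - r) < 1e-9) ? r : p;
}

static void get_dims3(const NumericVector& x, int& H, int& W, int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 2) { H = d[0]; W = d[1]; C = 1; }
  else { H = d[0]; W = d[1]; C = d[2]; }
}

// Gather the input patches into a (Ho*Wo) x (kh*kw*C) matrix. Out-of-range
// samples are reflected (pad_mode 1) or zero (pad_mode 0).
static arma::mat im2col(const double* x, int H, int W, int C,
                        int kh, int kw, int stride, int pad, int pad_mode,
                        int Ho, int Wo) {
  arma::mat M(Ho * (size_t)Wo, kh * (size_t)kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        size_t col = p + (size_t)kh * (q + (size_t)kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          int jin = jo * stride - pad + q;
          for (int io = 0; io < Ho; ++io) {
            int iin = io * stride - pad + p;
            int ii = iin, jj = jin;
            if (pad_mode == 1) { ii = reflect_idx(iin, H); jj = reflect_idx(jin, W); }
            else if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            M(io + (size_t)Ho * jo, col) = xc[ii + (size_t)H * jj];
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int pad_mode) {
  int H, W, C; get_dims3(x, H, W, C);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  arma::mat M = im2col(REAL(x), H, W, C, kh, kw, stride, pad, pad_mode, Ho, Wo);
  arma::mat W2(const_cast<double*>(REAL(w)), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat Y = M * W2;
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  NumericVector out(Y.memptr(), Y.memptr() + Y.n_elem);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad, int pad_mode, bool need_gx) {
  int H, W, C; get_dims3(x, H, W, C);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  arma::mat M = im2col(REAL(x), H, W, C, kh, kw, stride, pad, pad_mode, Ho, Wo);
  arma::mat G(const_cast<double*>(REAL(gy)), (size_t)Ho * Wo, Cout, false, true);
  arma::mat W2(const_cast<double*>(REAL(w)), (size_t)kh * kw * Cin, Cout, false, true);

  arma::mat gW = M.t() * G;                       // (kh*kw*Cin) x Cout
  arma::rowvec gb = arma::sum(G, 0);

  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) {
  arma::mat gM = G * W2.t();                      // (Ho*Wo) x (kh*kw*Cin)
  gx.attr("dim") = x.attr("dim");
  double* gxp = REAL(gx);
  for (int c = 0; c < C; ++c) {
    double* gxc = gxp + (size_t)H * W * c;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        size_t col = p + (size_t)kh * (q + (size_t)kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          int jin = jo * stride - pad + q;
          for (int io = 0; io < Ho; ++io) {
            int iin = io * stride - pad + p;
            int ii = iin, jj = jin;
            if (pad_mode == 1) { ii = reflect_idx(iin, H); jj = reflect_idx(jin, W); }
            else if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            gxc[ii + (size_t)H * jj] += gM(io + (size_t)Ho * jo, col);
          }
        }
      }
    }
  }
  }
  NumericVector gwv(gW.memptr(), gW.memptr() + gW.n_elem);
  gwv.attr("dim") = w.attr("dim");
  NumericVector gbv(Cout);
  for (int co = 0; co < Cout; ++co) gbv[co] = gb[co];
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// Forward pass that also returns the im2col patch matrix so the backward
// pass can reuse it (training-path variant of cpp_conv2d_fw).
// [[Rcpp::export]]
List cpp_conv2d_fwm(NumericVector x, NumericVector w, NumericVector b,
                    int stride, int pad, int pad_mode) {
  int H, W, C; get_dims3(x, H, W, C);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  arma::mat M = im2col(REAL(x), H, W, C, kh, kw, stride, pad, pad_mode, Ho, Wo);
  arma::mat W2(const_cast<double*>(REAL(w)), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat Y = M * W2;
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  NumericVector out(Y.memptr(), Y.memptr() + Y.n_elem);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  NumericMatrix Mout(M.n_rows, M.n_cols);
  std::copy(M.memptr(), M.memptr() + M.n_elem, Mout.begin());
  return List::create(_["y"] = out, _["M"] = Mout);
}

// Backward pass reusing the cached patch matrix from cpp_conv2d_fwm.
// [[Rcpp::export]]
List cpp_conv2d_bwm(NumericMatrix Mc, IntegerVector xdim, NumericVector w,
                    NumericVector gy, int stride, int pad, int pad_mode,
                    bool need_gx) {
  int H = xdim[0], W = xdim[1];
  int C = xdim.size() > 2 ? xdim[2] : 1;
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  arma::mat M(Mc.begin(), Mc.nrow(), Mc.ncol(), false, true);
  arma::mat G(const_cast<double*>(REAL(gy)), (size_t)Ho * Wo, Cout, false, true);
  arma::mat W2(const_cast<double*>(REAL(w)), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat gW = M.t() * G;
  arma::rowvec gb = arma::sum(G, 0);
  NumericVector gx(need_gx ? (size_t)H * W * C : 0);
  if (need_gx) {
    arma::mat gM = G * W2.t();
    gx.attr("dim") = IntegerVector::create(H, W, C);
    double* gxp = REAL(gx);
    for (int c = 0; c < C; ++c) {
      double* gxc = gxp + (size_t)H * W * c;
      for (int q = 0; q < kw; ++q) {
        for (int p = 0; p < kh; ++p) {
          size_t col = p + (size_t)kh * (q + (size_t)kw * c);
          for (int jo = 0; jo < Wo; ++jo) {
            int jin = jo * stride - pad + q;
            for (int io = 0; io < Ho; ++io) {
              int iin = io * stride - pad + p;
              int ii = iin, jj = jin;
              if (pad_mode == 1) { ii = reflect_idx(iin, H); jj = reflect_idx(jin, W); }
              else if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
              gxc[ii + (size_t)H * jj] += gM(io + (size_t)Ho * jo, col);
            }
          }
        }
      }
    }
  }
  NumericVector gwv(gW.memptr(), gW.memptr() + gW.n_elem);
  gwv.attr("dim") = w.attr("dim");
  NumericVector gbv(Cout);
  for (int co = 0; co < Cout; ++co) gbv[co] = gb[co];
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// Bilinear sampling at absolute normalized coordinates (align-corners
// convention: -1 and 1 are the centers of the first and last pixel).
// grid has dims (Ho, Wo, 2) with channel 1 = x (width), channel 2 = y (height).
// pad_mode: 0 = zeros, 1 = border.
// [[Rcpp::export]]
NumericVector cpp_grid_sample_fw(NumericVector x, NumericVector grid, int pad_mode) {
  int H, W, C; get_dims3(x, H, W, C);
  IntegerVector gd = grid.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  const double* xp = REAL(x);
  const double* gp = REAL(grid);
  size_t npix = (size_t)Ho * Wo;
  NumericVector out((size_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  double* op = REAL(out);
  for (size_t k = 0; k < npix; ++k) {
    double px = snap_coord((gp[k] + 1.0) * 0.5 * (W - 1));
    double py = snap_coord((gp[k + npix] + 1.0) * 0.5 * (H - 1));
    if (pad_mode == 1) {
      px = std::min(std::max(px, 0.0), (double)(W - 1));
      py = std::min(std::max(py, 0.0), (double)(H - 1));
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
    double wx = px - x0, wy = py - y0;
    for (int dy = 0; dy <= 1; ++dy) {
      for (int dx = 0; dx <= 1; ++dx) {
        int xi = x0 + dx, yi = y0 + dy;
        double wgt = (dx ? wx : 1 - wx) * (dy ? wy : 1 - wy);
        if (wgt == 0.0) continue;
        if (pad_mode == 1) {
          xi = std::min(std::max(xi, 0), W - 1);
          yi = std::min(std::max(yi, 0), H - 1);
        } else if (xi < 0 || xi >= W || yi < 0 || yi >= H) continue;
        for (int c = 0; c < C; ++c)
          op[k + npix * c] += wgt * xp[yi + (size_t)H * xi + (size_t)H * W * c];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_grid_sample_bw(NumericVector x, NumericVector grid, NumericVector gy,
                        int pad_mode) {
  int H, W, C; get_dims3(x, H, W, C);
  IntegerVector gd = grid.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  const double* xp = REAL(x);
  const double* gp = REAL(grid);
  const double* gyp = REAL(gy);
  size_t npix = (size_t)Ho * Wo;
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector gg(grid.size()); gg.attr("dim") = grid.attr("dim");
  double* gxp = REAL(gx);
  double* ggp = REAL(gg);
  for (size_t k = 0; k < npix; ++k) {
    double px = snap_coord((gp[k] + 1.0) * 0.5 * (W - 1));
    double py = snap_coord((gp[k + npix] + 1.0) * 0.5 * (H - 1));
    bool inx = true, iny = true;
    if (pad_mode == 1) {
      if (px < 0 || px > W - 1) inx = false;
      if (py < 0 || py > H - 1) iny = false;
      px = std::min(std::max(px, 0.0), (double)(W - 1));
      py = std::min(std::max(py, 0.0), (double)(H - 1));
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
    double wx = px - x0, wy = py - y0;
    double dpx = 0.0, dpy = 0.0;
    for (int dy = 0; dy <= 1; ++dy) {
      for (int dx = 0; dx <= 1; ++dx) {
        int xi = x0 + dx, yi = y0 + dy;
        double wgt = (dx ? wx : 1 - wx) * (dy ? wy : 1 - wy);
        double dwdx = (dx ? 1.0 : -1.0) * (dy ? wy : 1 - wy);
        double dwdy = (dy ? 1.0 : -1.0) * (dx ? wx : 1 - wx);
        int xc = xi, yc = yi;
        if (pad_mode == 1) {
          xc = std::min(std::max(xi, 0), W - 1);
          yc = std::min(std::max(yi, 0), H - 1);
        } else if (xi < 0 || xi >= W || yi < 0 || yi >= H) continue;
        for (int c = 0; c < C; ++c) {
          double g = gyp[k + npix * c];
          if (g == 0.0) continue;
          double v = xp[yc + (size_t)H * xc + (size_t)H * W * c];
          gxp[yc + (size_t)H * xc + (size_t)H * W * c] += g * wgt;
          dpx += g * dwdx * v;
          dpy += g * dwdy * v;
        }
      }
    }
    if (!inx) dpx = 0.0;
    if (!iny) dpy = 0.0;
    ggp[k]        = dpx * 0.5 * (W - 1);
    ggp[k + npix] = dpy * 0.5 * (H - 1);
  }
  return List::create(_["gx"] = gx, _["ggrid"] = gg);
}
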