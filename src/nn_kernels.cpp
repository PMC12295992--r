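// Low-level numerical kernels for the network: 3D convolution via
// im2col + GEMM, depthwise 3D convolution, trilinear resizing and
// trilinear grid sampling, each with the adjoint/backward companions
// needed for reverse-mode differentiation. Feature maps are R arrays
// with dims (H, W, D, C), column-major.

#include <Rcpp.h>

using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Copy x into a zero-padded buffer (per channel).
static std::vector<double> pad_input(const double* x, int H, int W, int D,
                                     int C, int pad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad, Dp = D + 2 * pad;
  std::vector<double> P((size_t)Hp * Wp * Dp * C, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* src = x + (size_t)H * W * D * c;
    double* dst = P.data() + (size_t)Hp * Wp * Dp * c;
    for (int d = 0; d < D; ++d)
      for (int w = 0; w < W; ++w)
        std::copy(src + (size_t)H * (w + (size_t)W * d),
                  src + (size_t)H * (w + (size_t)W * d) + H,
                  dst + pad + (size_t)Hp * (w + pad + (size_t)Wp * (d + pad)));
  }
  return P;
}

// Direct 3D convolution: per-tap axpy over the padded input. wm is
// (k^3*Cin x Cout) with row index kk + k^3*ci, kk = kh + k*kw + k*k*kd.
// [[Rcpp::export(name = ".cx_conv3d_fwd")]]
NumericVector cx_conv3d_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix wm, NumericVector bias,
                            int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const int Do = out_dim(D, k, stride, pad);
  const int Cout = wm.ncol();
  const size_t Nout = (size_t)Ho * Wo * Do;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::vector<double> P = pad_input(x.begin(), H, W, D, C, pad);
  const size_t chP = (size_t)Hp * Wp * (D + 2 * pad);
  NumericVector res(Nout * Cout);
  double* out = res.begin();
  for (int co = 0; co < Cout; ++co)
    std::fill(out + Nout * co, out + Nout * (co + 1), bias[co]);
  for (int ci = 0; ci < C; ++ci) {
    const double* Pc = P.data() + chP * ci;
    for (int co = 0; co < Cout; ++co) {
      double* oc = out + Nout * co;
      for (int kd = 0; kd < k; ++kd)
      for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const double wv = wm(kh + k * kw + k * k * kd + k * k * k * ci, co);
        if (wv == 0.0) continue;
        size_t o = 0;
        for (int od = 0; od < Do; ++od) {
          const size_t dbase = (size_t)Hp * Wp * (od * stride + kd);
          for (int ow = 0; ow < Wo; ++ow) {
            const double* src = Pc + dbase + (size_t)Hp * (ow * stride + kw) + kh;
            double* dst = oc + o;
            if (stride == 1) {
              for (int oh = 0; oh < Ho; ++oh) dst[oh] += wv * src[oh];
            } else {
              for (int oh = 0; oh < Ho; ++oh) dst[oh] += wv * src[(size_t)oh * stride];
            }
            o += Ho;
          }
        }
      }
    }
  }
  res.attr("dim") = IntegerVector::create(Ho, Wo, Do, Cout);
  return res;
}

// [[Rcpp::export(name = ".cx_conv3d_bwd")]]
List cx_conv3d_bwd(NumericVector x, IntegerVector dims,
                   NumericMatrix wm, NumericVector dout,
                   int k, int stride, int pad, bool need_dx = true) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const int Do = out_dim(D, k, stride, pad);
  const int Cout = wm.ncol();
  const size_t Nout = (size_t)Ho * Wo * Do;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad, Dp = D + 2 * pad;
  std::vector<double> P = pad_input(x.begin(), H, W, D, C, pad);
  std::vector<double> dP((size_t)Hp * Wp * Dp * C, 0.0);
  const size_t chP = (size_t)Hp * Wp * Dp;
  NumericMatrix dW(wm.nrow(), wm.ncol());
  NumericVector db(Cout);
  const double* g = dout.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* gc = g + Nout * co;
    double acc = 0.0;
    for (size_t i = 0; i < Nout; ++i) acc += gc[i];
    db[co] = acc;
  }
  for (int ci = 0; ci < C; ++ci) {
    const double* Pc = P.data() + chP * ci;
    double* dPc = dP.data() + chP * ci;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = g + Nout * co;
      for (int kd = 0; kd < k; ++kd)
      for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int wrow = kh + k * kw + k * k * kd + k * k * k * ci;
        const double wv = wm(wrow, co);
        double wacc = 0.0;
        size_t o = 0;
        for (int od = 0; od < Do; ++od) {
          const size_t dbase = (size_t)Hp * Wp * (od * stride + kd);
          for (int ow = 0; ow < Wo; ++ow) {
            const size_t base = dbase + (size_t)Hp * (ow * stride + kw) + kh;
            const double* src = Pc + base;
            double* ddst = dPc + base;
            const double* gg = gc + o;
            if (need_dx && stride == 1) {
              for (int oh = 0; oh < Ho; ++oh) {
                wacc += src[oh] * gg[oh];
                ddst[oh] += wv * gg[oh];
              }
            } else if (need_dx) {
              for (int oh = 0; oh < Ho; ++oh) {
                wacc += src[(size_t)oh * stride] * gg[oh];
                ddst[(size_t)oh * stride] += wv * gg[oh];
              }
            } else if (stride == 1) {
              for (int oh = 0; oh < Ho; ++oh) wacc += src[oh] * gg[oh];
            } else {
              for (int oh = 0; oh < Ho; ++oh)
                wacc += src[(size_t)oh * stride] * gg[oh];
            }
            o += Ho;
          }
        }
        dW(wrow, co) += wacc;
      }
    }
  }
  // crop padded gradient back to input dims
  NumericVector dx(need_dx ? (size_t)H * W * D * C : 0);
  if (need_dx) for (int c = 0; c < C; ++c) {
    double* dst = dx.begin() + (size_t)H * W * D * c;
    const double* src = dP.data() + chP * c;
    for (int d = 0; d < D; ++d)
      for (int w = 0; w < W; ++w)
        std::copy(src + pad + (size_t)Hp * (w + pad + (size_t)Wp * (d + pad)),
                  src + pad + (size_t)Hp * (w + pad + (size_t)Wp * (d + pad)) + H,
                  dst + (size_t)H * (w + (size_t)W * d));
  }
  if (need_dx) dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = db);
}

// Depthwise conv: weights (k^3 x C), one filter per channel.
// [[Rcpp::export(name = ".cx_dwconv3d_fwd")]]
NumericVector cx_dwconv3d_fwd(NumericVector x, IntegerVector dims,
                              NumericMatrix wm, NumericVector bias,
                              int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const int Do = out_dim(D, k, stride, pad);
  const int HW = H * W, HWD = H * W * D;
  NumericVector res((size_t)Ho * Wo * Do * C);
  double* out = res.begin();
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* w = &wm(0, c);
    const double* src = xp + (size_t)HWD * c;
    double* dst = out + (size_t)Ho * Wo * Do * c;
    size_t o = 0;
    for (int od = 0; od < Do; ++od)
    for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh, ++o) {
      double acc = bias[c];
      int kk = 0;
      for (int kd = 0; kd < k; ++kd) {
        const int d = od * stride - pad + kd;
        for (int kw = 0; kw < k; ++kw) {
          const int wv = ow * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh, ++kk) {
            const int h = oh * stride - pad + kh;
            if (d >= 0 && d < D && wv >= 0 && wv < W && h >= 0 && h < H)
              acc += w[kk] * src[h + H * wv + HW * d];
          }
        }
      }
      dst[o] = acc;
    }
  }
  res.attr("dim") = IntegerVector::create(Ho, Wo, Do, C);
  return res;
}

// [[Rcpp::export(name = ".cx_dwconv3d_bwd")]]
List cx_dwconv3d_bwd(NumericVector x, IntegerVector dims,
                     NumericMatrix wm, NumericVector dout,
                     int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const int Do = out_dim(D, k, stride, pad);
  const int HW = H * W, HWD = H * W * D;
  NumericVector dx((size_t)HWD * C);
  NumericMatrix dW(wm.nrow(), wm.ncol());
  NumericVector db(C);
  const double* xp = x.begin();
  const double* g = dout.begin();
  for (int c = 0; c < C; ++c) {
    const double* w = &wm(0, c);
    const double* src = xp + (size_t)HWD * c;
    double* dsx = dx.begin() + (size_t)HWD * c;
    const double* gc = g + (size_t)Ho * Wo * Do * c;
    double* dwc = &dW(0, c);
    double accb = 0.0;
    size_t o = 0;
    for (int od = 0; od < Do; ++od)
    for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh, ++o) {
      const double gv = gc[o];
      accb += gv;
      int kk = 0;
      for (int kd = 0; kd < k; ++kd) {
        const int d = od * stride - pad + kd;
        for (int kw = 0; kw < k; ++kw) {
          const int wv = ow * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh, ++kk) {
            const int h = oh * stride - pad + kh;
            if (d >= 0 && d < D && wv >= 0 && wv < W && h >= 0 && h < H) {
              const size_t idx = h + H * wv + HW * d;
              dsx[idx] += gv * w[kk];
              dwc[kk] += gv * src[idx];
            }
          }
        }
      }
    }
    db[c] = accb;
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = db);
}

// Trilinear resize with half-pixel-center alignment.
// [[Rcpp::export(name = ".cx_resize3d_fwd")]]
NumericVector cx_resize3d_fwd(NumericVector x, IntegerVector dims,
                              IntegerVector odims) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int Ho = odims[0], Wo = odims[1], Do = odims[2];
  const int HW = H * W, HWD = H * W * D;
  NumericVector res((size_t)Ho * Wo * Do * C);
  std::vector<int> h0(Ho), w0(Wo), d0(Do);
  std::vector<double> hf(Ho), wf(Wo), df(Do);
  auto prep = [](int no, int ni, std::vector<int>& i0, std::vector<double>& fr) {
    for (int o = 0; o < no; ++o) {
      double v = (o + 0.5) * (double)ni / no - 0.5;
      if (v < 0) v = 0;
      if (v > ni - 1) v = ni - 1;
      int i = (int)std::floor(v);
      if (i > ni - 2) i = ni - 2;
      if (i < 0) i = 0;
      i0[o] = i;
      fr[o] = (ni == 1) ? 0.0 : v - i;
    }
  };
  prep(Ho, H, h0, hf); prep(Wo, W, w0, wf); prep(Do, D, d0, df);
  for (int c = 0; c < C; ++c) {
    const double* src = x.begin() + (size_t)HWD * c;
    double* dst = res.begin() + (size_t)Ho * Wo * Do * c;
    size_t o = 0;
    for (int od = 0; od < Do; ++od)
    for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh, ++o) {
      const int a = h0[oh], b = w0[ow], d = d0[od];
      const double fa = hf[oh], fb = wf[ow], fd = df[od];
      const int a1 = (H > 1) ? a + 1 : a, b1 = (W > 1) ? b + 1 : b, d1 = (D > 1) ? d + 1 : d;
      double v = 0.0;
      v += src[a  + H * b  + HW * d ] * (1 - fa) * (1 - fb) * (1 - fd);
      v += src[a1 + H * b  + HW * d ] * fa * (1 - fb) * (1 - fd);
      v += src[a  + H * b1 + HW * d ] * (1 - fa) * fb * (1 - fd);
      v += src[a1 + H * b1 + HW * d ] * fa * fb * (1 - fd);
      v += src[a  + H * b  + HW * d1] * (1 - fa) * (1 - fb) * fd;
      v += src[a1 + H * b  + HW * d1] * fa * (1 - fb) * fd;
      v += src[a  + H * b1 + HW * d1] * (1 - fa) * fb * fd;
      v += src[a1 + H * b1 + HW * d1] * fa * fb * fd;
      dst[o] = v;
    }
  }
  res.attr("dim") = IntegerVector::create(Ho, Wo, Do, C);
  return res;
}

// Adjoint of trilinear resize (scatter-add of the same weights).
// [[Rcpp::export(name = ".cx_resize3d_bwd")]]
NumericVector cx_resize3d_bwd(NumericVector dout, IntegerVector odims,
                              IntegerVector dims) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int Ho = odims[0], Wo = odims[1], Do = odims[2];
  const int HW = H * W, HWD = H * W * D;
  NumericVector dx((size_t)HWD * C);
  std::vector<int> h0(Ho), w0(Wo), d0(Do);
  std::vector<double> hf(Ho), wf(Wo), df(Do);
  auto prep = [](int no, int ni, std::vector<int>& i0, std::vector<double>& fr) {
    for (int o = 0; o < no; ++o) {
      double v = (o + 0.5) * (double)ni / no - 0.5;
      if (v < 0) v = 0;
      if (v > ni - 1) v = ni - 1;
      int i = (int)std::floor(v);
      if (i > ni - 2) i = ni - 2;
      if (i < 0) i = 0;
      i0[o] = i;
      fr[o] = (ni == 1) ? 0.0 : v - i;
    }
  };
  prep(Ho, H, h0, hf); prep(Wo, W, w0, wf); prep(Do, D, d0, df);
  for (int c = 0; c < C; ++c) {
    double* dst = dx.begin() + (size_t)HWD * c;
    const double* g = dout.begin() + (size_t)Ho * Wo * Do * c;
    size_t o = 0;
    for (int od = 0; od < Do; ++od)
    for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh, ++o) {
      const int a = h0[oh], b = w0[ow], d = d0[od];
      const double fa = hf[oh], fb = wf[ow], fd = df[od];
      const int a1 = (H > 1) ? a + 1 : a, b1 = (W > 1) ? b + 1 : b, d1 = (D > 1) ? d + 1 : d;
      const double gv = g[o];
      dst[a  + H * b  + HW * d ] += gv * (1 - fa) * (1 - fb) * (1 - fd);
      dst[a1 + H * b  + HW * d ] += gv * fa * (1 - fb) * (1 - fd);
      dst[a  + H * b1 + HW * d ] += gv * (1 - fa) * fb * (1 - fd);
      dst[a1 + H * b1 + HW * d ] += gv * fa * fb * (1 - fd);
      dst[a  + H * b  + HW * d1] += gv * (1 - fa) * (1 - fb) * fd;
      dst[a1 + H * b  + HW * d1] += gv * fa * (1 - fb) * fd;
      dst[a  + H * b1 + HW * d1] += gv * (1 - fa) * fb * fd;
      dst[a1 + H * b1 + HW * d1] += gv * fa * fb * fd;
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// Trilinear grid sampling. coords: (M x 3) normalized per-axis in [0,1]
// (voxel center i maps to (i + 0.5)/n); out-of-range coords clamp to the
// border, where the coordinate gradient is zero.
// [[Rcpp::export(name = ".cx_gridsample_fwd")]]
NumericMatrix cx_gridsample_fwd(NumericVector x, IntegerVector dims,
                                NumericMatrix coords) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int HW = H * W, HWD = H * W * D;
  const int M = coords.nrow();
  NumericMatrix out(M, C);
  const int n[3] = {H, W, D};
  for (int m = 0; m < M; ++m) {
    double v[3]; int i0[3]; double f[3];
    for (int a = 0; a < 3; ++a) {
      double t = coords(m, a) * n[a] - 0.5;
      if (t < 0) t = 0;
      if (t > n[a] - 1) t = n[a] - 1;
      int i = (int)std::floor(t);
      if (i > n[a] - 2) i = n[a] - 2;
      if (i < 0) i = 0;
      i0[a] = i; f[a] = (n[a] == 1) ? 0.0 : t - i; v[a] = t;
    }
    (void)v;
    const int a = i0[0], b = i0[1], d = i0[2];
    const int a1 = (H > 1) ? a + 1 : a, b1 = (W > 1) ? b + 1 : b, d1 = (D > 1) ? d + 1 : d;
    const double fa = f[0], fb = f[1], fd = f[2];
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + (size_t)HWD * c;
      double val = 0.0;
      val += src[a  + H * b  + HW * d ] * (1 - fa) * (1 - fb) * (1 - fd);
      val += src[a1 + H * b  + HW * d ] * fa * (1 - fb) * (1 - fd);
      val += src[a  + H * b1 + HW * d ] * (1 - fa) * fb * (1 - fd);
      val += src[a1 + H * b1 + HW * d ] * fa * fb * (1 - fd);
      val += src[a  + H * b  + HW * d1] * (1 - fa) * (1 - fb) * fd;
      val += src[a1 + H * b  + HW * d1] * fa * (1 - fb) * fd;
      val += src[a  + H * b1 + HW * d1] * (1 - fa) * fb * fd;
      val += src[a1 + H * b1 + HW * d1] * fa * fb * fd;
      out(m, c) = val;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cx_gridsample_bwd")]]
List cx_gridsample_bwd(NumericVector x, IntegerVector dims,
                       NumericMatrix coords, NumericMatrix dout) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int HW = H * W, HWD = H * W * D;
  const int M = coords.nrow();
  NumericVector dx((size_t)HWD * C);
  NumericMatrix dc(M, 3);
  const int n[3] = {H, W, D};
  for (int m = 0; m < M; ++m) {
    int i0[3]; double f[3]; bool interior[3];
    for (int a = 0; a < 3; ++a) {
      double t = coords(m, a) * n[a] - 0.5;
      interior[a] = (t > 0.0 && t < n[a] - 1.0 && n[a] > 1);
      if (t < 0) t = 0;
      if (t > n[a] - 1) t = n[a] - 1;
      int i = (int)std::floor(t);
      if (i > n[a] - 2) i = n[a] - 2;
      if (i < 0) i = 0;
      i0[a] = i; f[a] = (n[a] == 1) ? 0.0 : t - i;
    }
    const int a = i0[0], b = i0[1], d = i0[2];
    const int a1 = (H > 1) ? a + 1 : a, b1 = (W > 1) ? b + 1 : b, d1 = (D > 1) ? d + 1 : d;
    const double fa = f[0], fb = f[1], fd = f[2];
    const size_t idx[8] = {
      (size_t)(a  + H * b  + HW * d ), (size_t)(a1 + H * b  + HW * d ),
      (size_t)(a  + H * b1 + HW * d ), (size_t)(a1 + H * b1 + HW * d ),
      (size_t)(a  + H * b  + HW * d1), (size_t)(a1 + H * b  + HW * d1),
      (size_t)(a  + H * b1 + HW * d1), (size_t)(a1 + H * b1 + HW * d1)};
    const double wgt[8] = {
      (1 - fa) * (1 - fb) * (1 - fd), fa * (1 - fb) * (1 - fd),
      (1 - fa) * fb * (1 - fd),       fa * fb * (1 - fd),
      (1 - fa) * (1 - fb) * fd,       fa * (1 - fb) * fd,
      (1 - fa) * fb * fd,             fa * fb * fd};
    // dW/dfa etc. for coordinate gradients
    const double dfa[8] = {-(1 - fb) * (1 - fd), (1 - fb) * (1 - fd),
                           -fb * (1 - fd), fb * (1 - fd),
                           -(1 - fb) * fd, (1 - fb) * fd,
                           -fb * fd, fb * fd};
    const double dfb[8] = {-(1 - fa) * (1 - fd), -fa * (1 - fd),
                           (1 - fa) * (1 - fd), fa * (1 - fd),
                           -(1 - fa) * fd, -fa * fd,
                           (1 - fa) * fd, fa * fd};
    const double dfd[8] = {-(1 - fa) * (1 - fb), -fa * (1 - fb),
                           -(1 - fa) * fb, -fa * fb,
                           (1 - fa) * (1 - fb), fa * (1 - fb),
                           (1 - fa) * fb, fa * fb};
    double g0 = 0, g1 = 0, g2 = 0;
    for (int c = 0; c < C; ++c) {
      const double gv = dout(m, c);
      double* dst = dx.begin() + (size_t)HWD * c;
      const double* src = x.begin() + (size_t)HWD * c;
      for (int q = 0; q < 8; ++q) {
        dst[idx[q]] += gv * wgt[q];
        const double xv = src[idx[q]];
        g0 += gv * dfa[q] * xv;
        g1 += gv * dfb[q] * xv;
        g2 += gv * dfd[q] * xv;
      }
    }
    dc(m, 0) = interior[0] ? g0 * H : 0.0;
    dc(m, 1) = interior[1] ? g1 * W : 0.0;
    dc(m, 2) = interior[2] ? g2 * D : 0.0;
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dcoords"] = dc);
}
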