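// Resampling kernels for geometric perturbations: affine and
// displacement-field warps (trilinear or Catmull-Rom cubic), separable
// Gaussian blur, and axis-aligned line blur. Volumes are (H, W, D)
// arrays; coordinates are continuous 0-based voxel indices. The border
// is handled by symmetric reflection (…x1 x0 | x0 x1…), which keeps
// symmetric normalized kernels mass-preserving.

#include <Rcpp.h>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

static inline double cubic_w(double t) {
  // Catmull-Rom (a = -0.5)
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return ((a + 2.0) * t - (a + 3.0)) * t * t + 1.0;
  if (t < 2.0) return (((t - 5.0) * t + 8.0) * t - 4.0) * a;
  return 0.0;
}

static double sample_tri(const double* x, const int* n, const double* p,
                         bool mirror, double cval) {
  int i0[3]; double f[3];
  for (int a = 0; a < 3; ++a) {
    if (!mirror && (p[a] < -0.5 || p[a] > n[a] - 0.5)) return cval;
    const int i = (int)std::floor(p[a]);
    i0[a] = i; f[a] = p[a] - i;
  }
  double v = 0.0;
  for (int q = 0; q < 8; ++q) {
    const int dh = q & 1, dw = (q >> 1) & 1, dd = (q >> 2) & 1;
    const double w = (dh ? f[0] : 1 - f[0]) * (dw ? f[1] : 1 - f[1]) *
                     (dd ? f[2] : 1 - f[2]);
    if (w == 0.0) continue;
    const int h = reflect_idx(i0[0] + dh, n[0]);
    const int ww = reflect_idx(i0[1] + dw, n[1]);
    const int d = reflect_idx(i0[2] + dd, n[2]);
    v += w * x[h + n[0] * ww + (size_t)n[0] * n[1] * d];
  }
  return v;
}

static double sample_cubic(const double* x, const int* n, const double* p,
                           bool mirror, double cval) {
  int i0[3]; double f[3];
  for (int a = 0; a < 3; ++a) {
    if (!mirror && (p[a] < -0.5 || p[a] > n[a] - 0.5)) return cval;
    const int i = (int)std::floor(p[a]);
    i0[a] = i; f[a] = p[a] - i;
  }
  double wh[4], wwv[4], wd[4];
  for (int q = -1; q <= 2; ++q) {
    wh[q + 1] = cubic_w(q - f[0]);
    wwv[q + 1] = cubic_w(q - f[1]);
    wd[q + 1] = cubic_w(q - f[2]);
  }
  double v = 0.0;
  for (int qd = -1; qd <= 2; ++qd) {
    const int d = reflect_idx(i0[2] + qd, n[2]);
    for (int qw = -1; qw <= 2; ++qw) {
      const int w = reflect_idx(i0[1] + qw, n[1]);
      const double wy = wwv[qw + 1] * wd[qd + 1];
      for (int qh = -1; qh <= 2; ++qh) {
        const int h = reflect_idx(i0[0] + qh, n[0]);
        v += wh[qh + 1] * wy * x[h + n[0] * w + (size_t)n[0] * n[1] * d];
      }
    }
  }
  return v;
}

// out(idx) = in(A %*% idx + t), idx 0-based voxel coordinates.
// [[Rcpp::export(name = ".cx_warp_affine")]]
NumericVector cx_warp_affine(NumericVector x, IntegerVector dims,
                             NumericMatrix A, NumericVector t,
                             bool cubic, bool mirror, double cval) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  NumericVector out((size_t)n[0] * n[1] * n[2]);
  size_t o = 0;
  for (int d = 0; d < n[2]; ++d)
  for (int w = 0; w < n[1]; ++w)
  for (int h = 0; h < n[0]; ++h, ++o) {
    const double idx[3] = {(double)h, (double)w, (double)d};
    double p[3];
    for (int a = 0; a < 3; ++a)
      p[a] = A(a, 0) * idx[0] + A(a, 1) * idx[1] + A(a, 2) * idx[2] + t[a];
    out[o] = cubic ? sample_cubic(x.begin(), n, p, mirror, cval)
                   : sample_tri(x.begin(), n, p, mirror, cval);
  }
  out.attr("dim") = IntegerVector::create(n[0], n[1], n[2]);
  return out;
}

// out(idx) = in(idx + disp(idx)); disp is (H, W, D, 3) in voxel units.
// [[Rcpp::export(name = ".cx_warp_field")]]
NumericVector cx_warp_field(NumericVector x, IntegerVector dims,
                            NumericVector disp, bool cubic, bool mirror,
                            double cval) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const size_t nv = (size_t)n[0] * n[1] * n[2];
  NumericVector out(nv);
  size_t o = 0;
  for (int d = 0; d < n[2]; ++d)
  for (int w = 0; w < n[1]; ++w)
  for (int h = 0; h < n[0]; ++h, ++o) {
    double p[3] = {h + disp[o], w + disp[o + nv], d + disp[o + 2 * nv]};
    out[o] = cubic ? sample_cubic(x.begin(), n, p, mirror, cval)
                   : sample_tri(x.begin(), n, p, mirror, cval);
  }
  out.attr("dim") = IntegerVector::create(n[0], n[1], n[2]);
  return out;
}

static void conv_axis(const double* x, double* out, const int* n, int axis,
                      const double* w, const int* off, int ntap) {
  const size_t strides[3] = {1, (size_t)n[0], (size_t)n[0] * n[1]};
  const size_t st = strides[axis];
  const int len = n[axis];
  for (int d = 0; d < n[2]; ++d)
  for (int wv = 0; wv < n[1]; ++wv)
  for (int h = 0; h < n[0]; ++h) {
    const int idx3[3] = {h, wv, d};
    const size_t base = h + (size_t)n[0] * wv + (size_t)n[0] * n[1] * d;
    const int pos = idx3[axis];
    const size_t rest = base - pos * st;
    double acc = 0.0;
    for (int j = 0; j < ntap; ++j)
      acc += w[j] * x[rest + (size_t)reflect_idx(pos + off[j], len) * st];
    out[base] = acc;
  }
}

// Separable Gaussian blur, sigma per axis in voxels (0 disables an axis).
// [[Rcpp::export(name = ".cx_gaussian_blur")]]
NumericVector cx_gaussian_blur(NumericVector x, IntegerVector dims,
                               NumericVector sigma) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const size_t nv = (size_t)n[0] * n[1] * n[2];
  NumericVector buf1(clone(x)), buf2(nv);
  double* a = buf1.begin();
  double* b = buf2.begin();
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * r + 1);
    std::vector<int> off(2 * r + 1);
    double tot = 0.0;
    for (int j = -r; j <= r; ++j) {
      w[j + r] = std::exp(-0.5 * j * j / (s * s));
      off[j + r] = j;
      tot += w[j + r];
    }
    for (auto& v : w) v /= tot;
    conv_axis(a, b, n, axis, w.data(), off.data(), 2 * r + 1);
    std::swap(a, b);
  }
  NumericVector out(a, a + nv);
  out.attr("dim") = IntegerVector::create(n[0], n[1], n[2]);
  return out;
}

// 1D convolution along one axis with explicit taps/offsets (line blur).
// [[Rcpp::export(name = ".cx_axis_conv")]]
NumericVector cx_axis_conv(NumericVector x, IntegerVector dims, int axis,
                           NumericVector taps, IntegerVector offsets) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  NumericVector out((size_t)n[0] * n[1] * n[2]);
  conv_axis(x.begin(), out.begin(), n, axis, taps.begin(),
            offsets.begin(), taps.size());
  out.attr("dim") = IntegerVector::create(n[0], n[1], n[2]);
  return out;
}
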