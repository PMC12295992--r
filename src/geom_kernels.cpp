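// Geometry kernels: point-to-polyline distances and tube rasterization.

#include <Rcpp.h>
using namespace Rcpp;

static inline double seg_dist(const double* p, const double* q0,
                              const double* q1, double* tproj) {
  double d[3], e[3];
  double qq = 0.0, pq = 0.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = q1[a] - q0[a];
    e[a] = p[a] - q0[a];
    qq += d[a] * d[a];
    pq += e[a] * d[a];
  }
  double t = (qq > 0.0) ? pq / qq : 0.0;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double s = 0.0;
  for (int a = 0; a < 3; ++a) {
    const double r = e[a] - t * d[a];
    s += r * r;
  }
  if (tproj) *tproj = t;
  return std::sqrt(s);
}

// Min distance from each row of P to the polyline with vertices Q
// (consecutive rows connected).
// [[Rcpp::export(name = ".cx_point_polyline_dist")]]
NumericVector cx_point_polyline_dist(NumericMatrix P, NumericMatrix Q) {
  const int n = P.nrow(), m = Q.nrow();
  NumericVector out(n);
  std::vector<double> q(3 * m);
  for (int j = 0; j < m; ++j)
    for (int a = 0; a < 3; ++a) q[3 * j + a] = Q(j, a);
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf;
    if (m == 1) {
      double s = 0;
      for (int a = 0; a < 3; ++a) { double r = p[a] - q[a]; s += r * r; }
      best = std::sqrt(s);
    }
    for (int j = 0; j + 1 < m; ++j) {
      const double dd = seg_dist(p, &q[3 * j], &q[3 * (j + 1)], nullptr);
      if (dd < best) best = dd;
    }
    out[i] = best;
  }
  return out;
}

// Rasterize a tube around a densely sampled curve. curve: (m x 3) world
// mm; radii: per-vertex tube radius (mm). A voxel is foreground when its
// center lies within the (linearly interpolated) radius of the nearest
// curve segment. Returns the binary mask and the distance-to-curve field
// (Inf outside the visited band).
// [[Rcpp::export(name = ".cx_rasterize_tube")]]
List cx_rasterize_tube(NumericMatrix curve, NumericVector radii,
                       IntegerVector dims, NumericVector spacing,
                       NumericVector origin) {
  const int H = dims[0], W = dims[1], D = dims[2];
  const int m = curve.nrow();
  const size_t nv = (size_t)H * W * D;
  NumericVector dist(nv, R_PosInf);
  NumericVector margin(nv, R_PosInf);
  const int HW = H * W;
  const int n[3] = {H, W, D};
  for (int j = 0; j + 1 < m; ++j) {
    double q0[3] = {curve(j, 0), curve(j, 1), curve(j, 2)};
    double q1[3] = {curve(j + 1, 0), curve(j + 1, 1), curve(j + 1, 2)};
    const double r0 = radii[j], r1 = radii[j + 1];
    const double rmax = std::max(r0, r1);
    int lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      const double cmin = std::min(q0[a], q1[a]) - rmax - spacing[a];
      const double cmax = std::max(q0[a], q1[a]) + rmax + spacing[a];
      lo[a] = std::max(0, (int)std::floor((cmin - origin[a]) / spacing[a] - 0.5));
      hi[a] = std::min(n[a] - 1, (int)std::ceil((cmax - origin[a]) / spacing[a] - 0.5));
    }
    for (int d = lo[2]; d <= hi[2]; ++d)
    for (int w = lo[1]; w <= hi[1]; ++w)
    for (int h = lo[0]; h <= hi[0]; ++h) {
      double p[3] = {origin[0] + (h + 0.5) * spacing[0],
                     origin[1] + (w + 0.5) * spacing[1],
                     origin[2] + (d + 0.5) * spacing[2]};
      double t;
      const double dd = seg_dist(p, q0, q1, &t);
      const size_t idx = h + H * w + (size_t)HW * d;
      if (dd < dist[idx]) dist[idx] = dd;
      const double mg = dd - (r0 + t * (r1 - r0));
      if (mg < margin[idx]) margin[idx] = mg;
    }
  }
  IntegerVector mask(nv);
  for (size_t i = 0; i < nv; ++i) mask[i] = (margin[i] <= 0.0) ? 1 : 0;
  mask.attr("dim") = IntegerVector::create(H, W, D);
  dist.attr("dim") = IntegerVector::create(H, W, D);
  return List::create(_["mask"] = mask, _["dist"] = dist);
}
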