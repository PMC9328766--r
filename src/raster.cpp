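#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize a tube: mark every voxel whose centre lies within `radius`
// (physical units) of the polyline `pts` (rows = points, columns =
// physical coordinates along the three array axes; voxel centre of
// 0-based index i is i * spacing). Ends are hemispherical caps (the
// marked set is a capsule), whose medial axis terminates exactly at
// the polyline endpoints.
// [[Rcpp::export]]
LogicalVector rasterize_tube_cpp(NumericMatrix pts, double radius,
                                 IntegerVector dims, NumericVector spacing) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector out(n, false);
  const double r2 = radius * radius;
  const int nseg = pts.nrow() - 1;
  for (int s = 0; s < std::max(nseg, 0) + (pts.nrow() == 1 ? 1 : 0); ++s) {
    double a1 = pts(s, 0), a2 = pts(s, 1), a3 = pts(s, 2);
    double b1 = a1, b2 = a2, b3 = a3;
    if (s < nseg) { b1 = pts(s + 1, 0); b2 = pts(s + 1, 1); b3 = pts(s + 1, 2); }
    double lo1 = std::min(a1, b1) - radius, hi1 = std::max(a1, b1) + radius;
    double lo2 = std::min(a2, b2) - radius, hi2 = std::max(a2, b2) + radius;
    double lo3 = std::min(a3, b3) - radius, hi3 = std::max(a3, b3) + radius;
    int i1lo = std::max(0, (int)std::floor(lo1 / spacing[0]));
    int i1hi = std::min(d1 - 1, (int)std::ceil(hi1 / spacing[0]));
    int i2lo = std::max(0, (int)std::floor(lo2 / spacing[1]));
    int i2hi = std::min(d2 - 1, (int)std::ceil(hi2 / spacing[1]));
    int i3lo = std::max(0, (int)std::floor(lo3 / spacing[2]));
    int i3hi = std::min(d3 - 1, (int)std::ceil(hi3 / spacing[2]));
    double u1 = b1 - a1, u2 = b2 - a2, u3 = b3 - a3;
    double uu = u1 * u1 + u2 * u2 + u3 * u3;
    for (int i3 = i3lo; i3 <= i3hi; ++i3)
      for (int i2 = i2lo; i2 <= i2hi; ++i2)
        for (int i1 = i1lo; i1 <= i1hi; ++i1) {
          double p1 = i1 * spacing[0], p2 = i2 * spacing[1], p3 = i3 * spacing[2];
          double w1 = p1 - a1, w2 = p2 - a2, w3 = p3 - a3;
          double t = uu > 0 ? (w1 * u1 + w2 * u2 + w3 * u3) / uu : 0.0;
          t = std::min(1.0, std::max(0.0, t));
          double q1 = w1 - t * u1, q2 = w2 - t * u2, q3 = w3 - t * u3;
          if (q1 * q1 + q2 * q2 + q3 * q3 <= r2)
            out[i1 + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3)] = true;
        }
  }
  return out;
}

// Separable Gaussian blur of a matrix with reflected boundaries.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // rows
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr;
        if (rr >= nr) rr = 2 * nr - 2 - rr;
        if (rr < 0) rr = 0;
        acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  // columns
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc;
        if (cc >= nc) cc = 2 * nc - 2 - cc;
        if (cc < 0) cc = 0;
        acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}
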