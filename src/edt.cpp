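#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e30;

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas) with physical sample spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double qp = q * w;
    double s;
    for (;;) {
      double vp = v[k] * w;
      s = ((f[q] + qp * qp) - (f[v[k]] + vp * vp)) / (2.0 * (qp - vp));
      if (s <= z[k] && k > 0) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qp = q * w;
    while (z[k + 1] < qp) ++k;
    double vp = v[k] * w;
    d[q] = (qp - vp) * (qp - vp) + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform of a 3D logical array:
// for every foreground voxel, the distance (in physical units given by
// spacing, one value per array dimension) to the nearest background
// voxel centre. Background voxels map to 0. A volume with no background
// returns Inf everywhere.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, g;
  // axis 1 (stride 1)
  f.resize(d1); g.resize(d1);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2) {
      R_xlen_t base = (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
      for (int i = 0; i < d1; ++i) f[i] = D[base + i];
      dt1d(f, g, d1, spacing[0]);
      for (int i = 0; i < d1; ++i) D[base + i] = g[i];
    }
  // axis 2 (stride d1)
  f.resize(d2); g.resize(d2);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i1 = 0; i1 < d1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)d1 * d2 * i3;
      for (int i = 0; i < d2; ++i) f[i] = D[base + (R_xlen_t)d1 * i];
      dt1d(f, g, d2, spacing[1]);
      for (int i = 0; i < d2; ++i) D[base + (R_xlen_t)d1 * i] = g[i];
    }
  // axis 3 (stride d1*d2)
  f.resize(d3); g.resize(d3);
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)d1 * i2;
      for (int i = 0; i < d3; ++i) f[i] = D[base + s3 * i];
      dt1d(f, g, d3, spacing[2]);
      for (int i = 0; i < d3; ++i) D[base + s3 * i] = g[i];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = D[i];
    out[i] = (v >= 1e29) ? R_PosInf : std::sqrt(v);
  }
  return out;
}
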