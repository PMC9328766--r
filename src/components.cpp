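#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// neighbour offsets for 6 / 18 / 26 connectivity in 3D
static int make_offsets(int connectivity, int offs[26][3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs[n][0] = dz; offs[n][1] = dy; offs[n][2] = dx; ++n;
      }
  return n;
}

// Label foreground components of a 3D logical array (column-major,
// dims = c(d1, d2, d3)) by breadth-first search. Labels start at 1 in
// scan order, so output is deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  int offs[26][3];
  const int noff = make_offsets(connectivity, offs);

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i1 = (int)(p % d1);
      int i2 = (int)((p / d1) % d2);
      int i3 = (int)(p / ((R_xlen_t)d1 * d2));
      for (int k = 0; k < noff; ++k) {
        int j1 = i1 + offs[k][0], j2 = i2 + offs[k][1], j3 = i3 + offs[k][2];
        if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
          continue;
        R_xlen_t q = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
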