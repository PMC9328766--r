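#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// 3D topological thinning: 6-subiteration directional peeling in the
// style of Lee, Kashyap & Chu, with endpoint preservation. A voxel is
// deletable only if it is a simple point, checked with the
// Malandain-Bertrand characterization:
//   (a) the foreground of the 26-neighbourhood (centre excluded) has
//       exactly one 26-connected component, and
//   (b) the background restricted to the 18-neighbourhood has exactly
//       one 6-connected component that touches a face neighbour.
// Deleting a simple point provably preserves digital topology, so the
// skeleton keeps the connectivity of the input. Candidates collected in
// each directional pass are deleted sequentially with a re-check, and
// the voxel order is fixed, making the result deterministic.

static inline int cidx(int a1, int a2, int a3) { return a1 + 3 * a2 + 9 * a3; }

// fill 3x3x3 patch of the mask around voxel (i1,i2,i3); outside = background
static void get_patch(const std::vector<char>& m, int d1, int d2, int d3,
                      int i1, int i2, int i3, char patch[27]) {
  for (int a3 = 0; a3 < 3; ++a3)
    for (int a2 = 0; a2 < 3; ++a2)
      for (int a1 = 0; a1 < 3; ++a1) {
        int j1 = i1 + a1 - 1, j2 = i2 + a2 - 1, j3 = i3 + a3 - 1;
        char v = 0;
        if (j1 >= 0 && j1 < d1 && j2 >= 0 && j2 < d2 && j3 >= 0 && j3 < d3)
          v = m[j1 + (size_t)d1 * (j2 + (size_t)d2 * j3)];
        patch[cidx(a1, a2, a3)] = v;
      }
}

static int n26_neighbours(const char patch[27]) {
  int n = 0;
  for (int c = 0; c < 27; ++c)
    if (c != 13 && patch[c]) ++n;
  return n;
}

static bool is_simple(const char patch[27]) {
  // (a) one 26-connected foreground component in N26 \ {centre}
  int comp[27];
  for (int c = 0; c < 27; ++c) comp[c] = 0;
  int nfg = 0, stack[27];
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !patch[c] || comp[c]) continue;
    ++nfg;
    if (nfg > 1) return false;
    int top = 0;
    comp[c] = 1;
    stack[top++] = c;
    while (top) {
      int p = stack[--top];
      int p1 = p % 3, p2 = (p / 3) % 3, p3 = p / 9;
      for (int a3 = p3 - 1; a3 <= p3 + 1; ++a3)
        for (int a2 = p2 - 1; a2 <= p2 + 1; ++a2)
          for (int a1 = p1 - 1; a1 <= p1 + 1; ++a1) {
            if (a1 < 0 || a1 > 2 || a2 < 0 || a2 > 2 || a3 < 0 || a3 > 2)
              continue;
            int q = cidx(a1, a2, a3);
            if (q == 13 || !patch[q] || comp[q]) continue;
            comp[q] = 1;
            stack[top++] = q;
          }
    }
  }
  if (nfg != 1) return false;

  // (b) one 6-connected background component in N18 touching a face
  //     neighbour of the centre
  int bcomp[27];
  for (int c = 0; c < 27; ++c) bcomp[c] = 0;
  int nbg = 0;
  static const int step[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int c = 0; c < 27; ++c) {
    int c1 = c % 3, c2 = (c / 3) % 3, c3 = c / 9;
    int manh = std::abs(c1 - 1) + std::abs(c2 - 1) + std::abs(c3 - 1);
    if (manh != 1) continue;            // seed only from face neighbours
    if (patch[c] || bcomp[c]) continue;
    ++nbg;
    if (nbg > 1) return false;
    int top = 0, stack2[27];
    bcomp[c] = 1;
    stack2[top++] = c;
    while (top) {
      int p = stack2[--top];
      int p1 = p % 3, p2 = (p / 3) % 3, p3 = p / 9;
      for (int k = 0; k < 6; ++k) {
        int a1 = p1 + step[k][0], a2 = p2 + step[k][1], a3 = p3 + step[k][2];
        if (a1 < 0 || a1 > 2 || a2 < 0 || a2 > 2 || a3 < 0 || a3 > 2)
          continue;
        int q = cidx(a1, a2, a3);
        int m = std::abs(a1 - 1) + std::abs(a2 - 1) + std::abs(a3 - 1);
        if (m == 0 || m > 2) continue;  // stay inside N18
        if (patch[q] || bcomp[q]) continue;
        bcomp[q] = 1;
        stack2[top++] = q;
      }
    }
  }
  return nbg == 1;
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t n = (size_t)d1 * d2 * d3;
  if ((size_t)mask.size() != n) stop("mask length does not match dims");
  std::vector<char> m(n);
  for (size_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  static const int dir[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  char patch[27];
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int i3 = 0; i3 < d3; ++i3)
        for (int i2 = 0; i2 < d2; ++i2)
          for (int i1 = 0; i1 < d1; ++i1) {
            size_t p = i1 + (size_t)d1 * (i2 + (size_t)d2 * i3);
            if (!m[p]) continue;
            int j1 = i1 + dir[d][0], j2 = i2 + dir[d][1], j3 = i3 + dir[d][2];
            bool border = !(j1 >= 0 && j1 < d1 && j2 >= 0 && j2 < d2 &&
                            j3 >= 0 && j3 < d3 &&
                            m[j1 + (size_t)d1 * (j2 + (size_t)d2 * j3)]);
            if (!border) continue;
            get_patch(m, d1, d2, d3, i1, i2, i3, patch);
            if (n26_neighbours(patch) <= 1) continue;  // endpoint or isolated
            if (is_simple(patch)) cand.push_back(p);
          }
      // sequential deletion with a simplicity re-check keeps topology
      // exact; endpoint-ness is intentionally judged only at collection
      // time, so voxels orphaned within the pass do not survive as spurs
      for (size_t k = 0; k < cand.size(); ++k) {
        size_t p = cand[k];
        int i1 = (int)(p % d1);
        int i2 = (int)((p / d1) % d2);
        int i3 = (int)(p / ((size_t)d1 * d2));
        get_patch(m, d1, d2, d3, i1, i2, i3, patch);
        if (!is_simple(patch)) continue;
        m[p] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}
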