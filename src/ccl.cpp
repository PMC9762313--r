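#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path compression.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Two-pass connected-components labeling over the array's linear (raster)
// order. dims has length 2 (y, x) or 3 (z, y, x); `full` selects
// 8/26-connectivity, otherwise 4/6. Output labels are 1..n, numbered by the
// first-encountered voxel of each component in raster order; 0 = background.
// [[Rcpp::export]]
IntegerVector ccl_label(LogicalVector mask, IntegerVector dims, bool full) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3) stop("ccl_label: dims must have length 2 or 3");
  const int d1 = dims[0];
  const int d2 = dims[1];
  const int d3 = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("ccl_label: mask size does not match dims");

  // backward neighbor offsets (strictly earlier in linear order)
  std::vector<int> off1, off2, off3; // deltas along axis 1 (fastest), 2, 3
  for (int dz = -1; dz <= 0; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (nd == 2 && dz != 0) continue;
        if (dz == 0 && dx == 0 && dy == 0) continue;
        // keep only offsets pointing to earlier linear indices
        long lin = (long)dz * d1 * d2 + (long)dx * d1 + dy;
        if (lin >= 0) continue;
        int manhattan = std::abs(dz) + std::abs(dx) + std::abs(dy);
        if (!full && manhattan != 1) continue;
        off1.push_back(dy); off2.push_back(dx); off3.push_back(dz);
      }

  std::vector<int> lab((size_t)n, 0);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // label 0 sentinel

  R_xlen_t idx = 0;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i, ++idx) {
        if (!mask[idx]) continue;
        int best = 0;
        for (size_t t = 0; t < off1.size(); ++t) {
          int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
            continue;
          R_xlen_t nb = (R_xlen_t)kk * d1 * d2 + (R_xlen_t)jj * d1 + ii;
          int nl = lab[nb];
          if (nl == 0) continue;
          int root = uf_find(parent, nl);
          if (best == 0) best = root;
          else if (root != best) {
            // union: attach larger root under smaller (keeps earliest label)
            int a = std::min(best, root), b = std::max(best, root);
            parent[b] = a;
            best = a;
          }
        }
        if (best == 0) {
          int nl = (int)parent.size();
          parent.push_back(nl);
          lab[idx] = nl;
        } else {
          lab[idx] = best;
        }
      }

  // resolve and renumber roots by first occurrence in raster order
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  IntegerVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    if (lab[p] == 0) { out[p] = 0; continue; }
    int root = uf_find(parent, lab[p]);
    if (newlab[root] == 0) newlab[root] = ++next;
    out[p] = newlab[root];
  }
  out.attr("n_labels") = next;
  return out;
}
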