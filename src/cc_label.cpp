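#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Label connected components of a 3D logical array (dim = slice, row, col;
// column-major as stored by R). connectivity = 6 (face) or 26 (face+edge+
// corner). A 2D problem is passed as a single-slice array, where 6 and 26
// reduce to in-plane 4- and 8-connectivity. Labels are assigned in raster
// scan order starting at 1; background stays 0.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector grid, int connectivity) {
  IntegerVector dims = grid.attr("dim");
  if (dims.size() != 3) stop("grid must be a 3D array");
  const int ns = dims[0], nr = dims[1], nc = dims[2];
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  // neighbour offsets
  std::vector<int> ds, dr, dc;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        ds.push_back(a); dr.push_back(b); dc.push_back(c);
      }
  const int noff = (int)ds.size();

  const R_xlen_t n = (R_xlen_t)ns * nr * nc;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!grid[idx] || labels[idx] != 0) continue;
    ++next;
    labels[idx] = next;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int s = (int)(cur % ns);
      int r = (int)((cur / ns) % nr);
      int c = (int)(cur / ((R_xlen_t)ns * nr));
      for (int k = 0; k < noff; ++k) {
        int s2 = s + ds[k], r2 = r + dr[k], c2 = c + dc[k];
        if (s2 < 0 || s2 >= ns || r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc)
          continue;
        R_xlen_t j = s2 + (R_xlen_t)ns * (r2 + (R_xlen_t)nr * c2);
        if (grid[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}
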