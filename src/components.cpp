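#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected foreground components of a logical matrix under
// 8-connectivity. Returns an integer matrix: 0 = background, components
// numbered 1..k in raster-scan order of their first-encountered pixel
// (row-major over columns, matching R's column-major storage transposed),
// which makes labelling deterministic for a given mask.
// [[Rcpp::export(name = ".label_components", rng = false)]]
IntegerMatrix label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  // scan column-major (R storage order): first pixel of a component is the
  // smallest (col, row) pair, stable across identical masks
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
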