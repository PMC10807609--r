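#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 4-connected component labeling of an integer image. Pixels with value
// `background` stay 0; pixels connect only when they share an edge AND the
// same input value. Labels are assigned in raster-scan order, so output is
// deterministic. BFS with an explicit stack (no recursion).
// [[Rcpp::export(name = ".cc_label4")]]
IntegerMatrix cc_label4(const IntegerMatrix& img, int background = 0) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (img(i, j) == background || lab(i, j) != 0) continue;
      const int val = img(i, j);
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        // 4-neighbours
        if (pi > 0 && lab(pi - 1, pj) == 0 && img(pi - 1, pj) == val) {
          lab(pi - 1, pj) = next; stack.push_back(p - 1);
        }
        if (pi + 1 < nr && lab(pi + 1, pj) == 0 && img(pi + 1, pj) == val) {
          lab(pi + 1, pj) = next; stack.push_back(p + 1);
        }
        if (pj > 0 && lab(pi, pj - 1) == 0 && img(pi, pj - 1) == val) {
          lab(pi, pj - 1) = next; stack.push_back(p - nr);
        }
        if (pj + 1 < nc && lab(pi, pj + 1) == 0 && img(pi, pj + 1) == val) {
          lab(pi, pj + 1) = next; stack.push_back(p + nr);
        }
      }
    }
  }
  return lab;
}
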