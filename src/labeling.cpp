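#include <Rcpp.h>
#include <vector>
#include "neighbors.h"
using namespace Rcpp;

// Connected-component labelling of a 3D binary volume by breadth-first
// search under 6/18/26 connectivity. Labels are 1..K in order of first
// (column-major) appearance; background is 0.

// [[Rcpp::export]]
List cpp_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);
  Offsets off = make_offsets(connectivity);
  const int no = (int)off.di.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % n1);
      int j = (int)((cur / n1) % n2);
      int k = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < no; ++t) {
        int ii = i + off.di[t], jj = j + off.dj[t], kk = k + off.dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
          continue;
        R_xlen_t q = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return List::create(_["labels"] = lab, _["count"] = next);
}
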