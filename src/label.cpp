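#include <Rcpp.h>
#include <vector>
#include <utility>

// Connected-component labeling of a binary mask under 8-connectivity
// (diagonal neighbours join), depth-first flood fill.

// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components8(const Rcpp::IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int cur = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != 0 && lab(i, j) == 0) {
        ++cur;
        lab(i, j) = cur;
        stack.push_back(std::make_pair(i, j));
        while (!stack.empty()) {
          int r = stack.back().first, c = stack.back().second;
          stack.pop_back();
          for (int dr = -1; dr <= 1; ++dr) {
            for (int dc = -1; dc <= 1; ++dc) {
              int rr = r + dr, cc = c + dc;
              if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
                  mask(rr, cc) != 0 && lab(rr, cc) == 0) {
                lab(rr, cc) = cur;
                stack.push_back(std::make_pair(rr, cc));
              }
            }
          }
        }
      }
    }
  }
  return lab;
}
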