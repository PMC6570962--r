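#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical mask by iterative flood fill.
// Components are numbered 1..N in raster-scan order (top row first, left to
// right) of each component's first pixel, matching the particle-index
// contract used throughout the package. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  const int nn = (connectivity == 4) ? 4 : 8;

  std::vector<int> stack_r, stack_c;
  stack_r.reserve(1024);
  stack_c.reserve(1024);
  int next_label = 0;

  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      lab(r, c) = next_label;
      stack_r.clear();
      stack_c.clear();
      stack_r.push_back(r);
      stack_c.push_back(c);
      while (!stack_r.empty()) {
        int cr = stack_r.back(); stack_r.pop_back();
        int cc = stack_c.back(); stack_c.pop_back();
        for (int k = 0; k < nn; ++k) {
          int nr = cr + dr[k], nc = cc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (!mask(nr, nc) || lab(nr, nc) != 0) continue;
          lab(nr, nc) = next_label;
          stack_r.push_back(nr);
          stack_c.push_back(nc);
        }
      }
    }
  }
  return lab;
}
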