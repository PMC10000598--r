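// 4-connected component labelling and hole filling for binary masks.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Labels 4-connected components of nonzero pixels 1..n (0 elsewhere).
// [[Rcpp::export(name = ".cc_label")]]
List cc_label(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> sizes;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      int sz = 0;
      stack.push_back(r + c * h);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % h, pc = p / h;
        ++sz;
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int nr = pr + dr[k], nc = pc + dc[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          if (mask(nr, nc) && !lab(nr, nc)) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * h);
          }
        }
      }
      sizes.push_back(sz);
    }
  }
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}

// Fills interior holes: zero pixels not 4-connected to the border become 1.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  std::vector<char> outside((size_t)h * w, 0);
  std::vector<int> stack;
  auto push = [&](int r, int c) {
    size_t i = (size_t)r + (size_t)c * h;
    if (!mask(r, c) && !outside[i]) {
      outside[i] = 1;
      stack.push_back(r + c * h);
    }
  };
  for (int c = 0; c < w; ++c) { push(0, c); push(h - 1, c); }
  for (int r = 0; r < h; ++r) { push(r, 0); push(r, w - 1); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int pr = p % h, pc = p / h;
    const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
    for (int k = 0; k < 4; ++k) {
      int nr = pr + dr[k], nc = pc + dc[k];
      if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
      push(nr, nc);
    }
  }
  LogicalMatrix out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      out(r, c) = mask(r, c) || !outside[(size_t)r + (size_t)c * h];
  return out;
}
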