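#include <Rcpp.h>
using namespace Rcpp;

// Count 4-connected components of nonzero pixels via iterative flood fill.
// [[Rcpp::export]]
int cpp_count_components(const IntegerMatrix& px) {
  int nr = px.nrow(), nc = px.ncol();
  std::vector<char> seen(nr * nc, 0);
  std::vector<int> stack;
  int comps = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (px[idx] == 0 || seen[idx]) continue;
      ++comps;
      stack.clear();
      stack.push_back(idx);
      seen[idx] = 1;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int rr = cur % nr, cc = cur / nr;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int i2 = c2 * nr + r2;
          if (px[i2] != 0 && !seen[i2]) { seen[i2] = 1; stack.push_back(i2); }
        }
      }
    }
  }
  return comps;
}

// Label 4-connected components (0 = background), used for per-object metadata.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& px) {
  int nr = px.nrow(), nc = px.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int comps = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (px[idx] == 0 || lab[idx] != 0) continue;
      ++comps;
      stack.clear();
      stack.push_back(idx);
      lab[idx] = comps;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int rr = cur % nr, cc = cur / nr;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int i2 = c2 * nr + r2;
          if (px[i2] != 0 && lab[i2] == 0) { lab[i2] = comps; stack.push_back(i2); }
        }
      }
    }
  }
  return lab;
}
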