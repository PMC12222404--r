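#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connectivity connected-component labelling of a binary 3D mask by
// iterative flood fill. Returns an integer volume with labels 1..K
// (0 = background).

// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::size_t n = (std::size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::size_t> stack;
  int next = 0;
  for (std::size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const std::size_t v = stack.back();
      stack.pop_back();
      const int i = (int)(v % nx);
      const int j = (int)((v / nx) % ny);
      const int k = (int)(v / ((std::size_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const std::size_t w = ii + (std::size_t)nx * (jj + (std::size_t)ny * kk);
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}
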