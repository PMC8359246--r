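#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected component labelling of a logical volume (BFS).
// [[Rcpp::export]]
IntegerVector connected_components_cpp(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<size_t> queue;
  long strides[6] = {-1, 1, -n1, n1, -(long)n1 * n2, (long)n1 * n2};
  for (size_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    cur++;
    queue.clear();
    queue.push_back(s);
    lab[s] = cur;
    while (!queue.empty()) {
      size_t v = queue.back();
      queue.pop_back();
      int i = (int)(v % n1), j = (int)((v / n1) % n2), k = (int)(v / ((size_t)n1 * n2));
      int coord[3] = {i, j, k}, dims[3] = {n1, n2, n3};
      for (int d = 0; d < 6; d++) {
        int ax = d / 2, dir = (d % 2) ? 1 : -1;
        if (coord[ax] + dir < 0 || coord[ax] + dir >= dims[ax]) continue;
        size_t w = (size_t)((long)v + strides[d]);
        if (mask[w] && !lab[w]) {
          lab[w] = cur;
          queue.push_back(w);
        }
      }
    }
  }
  return lab;
}
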