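#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Two-pass union-find connected-component labeling on a binary mask.
// Labels are compacted to 1..K in first-pixel (column-major) order.
static int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> parent;
  parent.push_back(0);
  int next_label = 0;

  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c)) continue;
      int neigh[4];
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0) {
        if (mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
        if (connectivity == 8) {
          if (r > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
          if (r + 1 < h && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
        }
      }
      if (nn == 0) {
        ++next_label;
        parent.push_back(next_label);
        lab(r, c) = next_label;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, neigh[k]);
        m = find_root(parent, m);
        for (int k = 0; k < nn; ++k) {
          int q = find_root(parent, neigh[k]);
          if (q != m) parent[std::max(q, m)] = std::min(q, m);
          m = std::min(q, m);
        }
        lab(r, c) = m;
      }
    }
  }

  std::vector<int> remap(next_label + 1, 0);
  int k = 0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      int l = lab(r, c);
      if (!l) continue;
      int root = find_root(parent, l);
      if (!remap[root]) remap[root] = ++k;
      lab(r, c) = remap[root];
    }
  return lab;
}
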