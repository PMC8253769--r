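#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labelling (4-connectivity) with union-find.
// Input: logical matrix; output: integer matrix of labels (0 = background),
// labels renumbered 1..k in first-encounter order.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // dummy so labels are 1-based
  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int up = (r > 0) ? lab(r - 1, c) : 0;
      int left = (c > 0) ? lab(r, c - 1) : 0;
      if (up == 0 && left == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else if (up != 0 && left != 0) {
        int ru = uf_find(parent, up), rl = uf_find(parent, left);
        int m = std::min(ru, rl);
        parent[ru] = m;
        parent[rl] = m;
        lab(r, c) = m;
      } else {
        lab(r, c) = (up != 0) ? up : left;
      }
    }
  }
  std::vector<int> remap(parent.size(), 0);
  int k = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) == 0) continue;
      int root = uf_find(parent, lab(r, c));
      if (remap[root] == 0) remap[root] = ++k;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
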