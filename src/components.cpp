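#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find.
// connectivity: 4 or 8 (8 is the package default everywhere).

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  parent.push_back(0);  // label 0 = background, self-parent
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // already-visited neighbours (scan order: column-major, r fast)
      int neigh[4];
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8) {
        if (r > 0 && c > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r < nr - 1 && c > 0 && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        int m = neigh[0];
        for (int i = 1; i < nn; ++i) m = std::min(m, neigh[i]);
        lab(r, c) = m;
        for (int i = 0; i < nn; ++i) uf_union(parent, m, neigh[i]);
      }
    }
  }

  // second pass: flatten labels to 1..k
  std::vector<int> remap(parent.size(), 0);
  int k = 0;
  for (size_t i = 1; i < parent.size(); ++i) {
    int root = uf_find(parent, (int)i);
    if (remap[root] == 0 && root == (int)i) remap[root] = ++k;
  }
  // roots found in order; non-roots inherit
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[uf_find(parent, lab(r, c))];
  lab.attr("n_components") = k;
  return lab;
}
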