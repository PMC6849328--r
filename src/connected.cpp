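#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass connected-component labelling with union-find.
// mask is a logical matrix; connectivity is 4 or 8.
// Returns an integer matrix with background 0 and components labelled
// 1..K in scan order (column-major, matching R's memory layout) of the
// first pixel of each component.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix &mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  int next = 0;

  // first pass: provisional labels, merging with already-seen neighbours
  // (up-left region in column-major order: same column above, previous
  // column same row, and for 8-connectivity the two diagonals in the
  // previous column)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = -1;
      int neigh[4][2] = {
        {r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}
      };
      int nn = (connectivity == 8) ? 4 : 2;
      for (int k = 0; k < nn; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best < 0) best = l - 1;
          else unite(parent, best, l - 1);
        }
      }
      if (best < 0) {
        parent.push_back(next);
        best = next++;
      }
      lab(r, c) = best + 1;
    }
  }

  // resolve roots and compact to 1..K in scan order of first appearance
  std::vector<int> remap(next, 0);
  int K = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l - 1);
      if (remap[root] == 0) remap[root] = ++K;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}

// Component pixel sizes for an existing label image (labels 1..K).
// [[Rcpp::export(name = ".cc_sizes")]]
IntegerVector cc_sizes(const IntegerMatrix &lab) {
  int K = 0;
  const int n = lab.size();
  for (int i = 0; i < n; ++i) if (lab[i] > K) K = lab[i];
  IntegerVector sizes(K);
  for (int i = 0; i < n; ++i) if (lab[i] > 0) sizes[lab[i] - 1]++;
  return sizes;
}
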