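#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a != b) parent[a > b ? a : b] = (a < b ? a : b);
}

// Connected-component labeling of a logical array of dim (n1, n2, n3).
// `offsets` holds one neighbor offset per row (d1, d2, d3); callers pass the
// scan-order-negative half of the neighborhood, which covers every adjacent
// pair exactly once because union is symmetric. Labels are positive integers
// in first-touch order; background stays 0.
// [[Rcpp::export]]
IntegerVector cc_label_core(LogicalVector mask, IntegerVector dims,
                            IntegerMatrix offsets) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> parent(n);
  IntegerVector lab(n);

  // provisional labels = own linear index
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  const int noff = offsets.nrow();
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (!mask[idx]) continue;
        for (int o = 0; o < noff; ++o) {
          int ii = i + offsets(o, 0);
          int jj = j + offsets(o, 1);
          int kk = k + offsets(o, 2);
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
            continue;
          R_xlen_t nidx = (R_xlen_t)ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
          if (mask[nidx]) uf_union(parent, (int)idx, (int)nidx);
        }
      }

  // compact labels in scan order of component roots
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) { lab[i] = 0; continue; }
    int root = uf_find(parent, (int)i);
    if (relabel[root] == 0) relabel[root] = ++next;
    lab[i] = relabel[root];
  }
  return lab;
}
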