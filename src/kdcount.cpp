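#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// KD-tree over the rows of an embedding matrix, used to count, for every
// template, how many templates lie within Chebyshev distance r. Nodes carry
// their bounding box so a range-count query can take whole subtrees at once
// (box inside query ball) or discard them (box disjoint from ball); only
// boundary leaves are scanned point by point.

namespace {

struct Node {
  int left = -1, right = -1;  // children; -1 for leaf
  int start = 0, end = 0;     // [start, end) into idx
  std::vector<double> lo, hi; // bounding box
};

struct KDTree {
  const double* x;            // column-major n x d
  int n, d;
  std::vector<int> idx;
  std::vector<Node> nodes;
  static const int LEAF = 16;

  double at(int i, int j) const { return x[i + (size_t)j * n]; }

  int build(int start, int end) {
    nodes.emplace_back();
    int self = (int)nodes.size() - 1;
    {
      Node& nd = nodes[self];
      nd.start = start; nd.end = end;
      nd.lo.assign(d, R_PosInf); nd.hi.assign(d, R_NegInf);
      for (int k = start; k < end; ++k)
        for (int j = 0; j < d; ++j) {
          double v = at(idx[k], j);
          if (v < nd.lo[j]) nd.lo[j] = v;
          if (v > nd.hi[j]) nd.hi[j] = v;
        }
    }
    if (end - start <= LEAF) return self;
    // split widest dimension at its median
    int dim = 0; double width = -1.0;
    for (int j = 0; j < d; ++j) {
      double w = nodes[self].hi[j] - nodes[self].lo[j];
      if (w > width) { width = w; dim = j; }
    }
    if (width <= 0.0) return self;  // all points identical: leaf
    int mid = (start + end) / 2;
    const double* xx = x; int nn = n;
    std::nth_element(idx.begin() + start, idx.begin() + mid, idx.begin() + end,
                     [xx, nn, dim](int a, int b) {
                       return xx[a + (size_t)dim * nn] < xx[b + (size_t)dim * nn];
                     });
    int l = build(start, mid);
    int r = build(mid, end);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  void init(const double* x_, int n_, int d_) {
    x = x_; n = n_; d = d_;
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(2 * n / LEAF + 4);
    build(0, n);
  }

  // count points with max_j |x[p, j] - q[j]| <= r
  int count(int node, const double* q, double r) const {
    const Node& nd = nodes[node];
    bool inside = true;
    for (int j = 0; j < d; ++j) {
      if (nd.lo[j] > q[j] + r || nd.hi[j] < q[j] - r) return 0;   // disjoint
      if (nd.lo[j] < q[j] - r || nd.hi[j] > q[j] + r) inside = false;
    }
    if (inside) return nd.end - nd.start;
    if (nd.left < 0) {  // boundary leaf: scan
      int c = 0;
      for (int k = nd.start; k < nd.end; ++k) {
        int p = idx[k];
        bool ok = true;
        for (int j = 0; j < d; ++j)
          if (std::fabs(at(p, j) - q[j]) > r) { ok = false; break; }
        c += ok;
      }
      return c;
    }
    return count(nd.left, q, r) + count(nd.right, q, r);
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cheb_range_counts")]]
IntegerVector cheb_range_counts(NumericMatrix X, double r) {
  int n = X.nrow(), d = X.ncol();
  if (n == 0) return IntegerVector(0);
  KDTree tree;
  tree.init(X.begin(), n, d);
  IntegerVector out(n);
  std::vector<double> q(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) q[j] = X(i, j);
    out[i] = tree.count(0, q.data(), r);
  }
  return out;
}
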