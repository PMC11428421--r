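// Exact nearest-neighbour search over 3-D point sets via a k-d tree.
// Contract: exact Euclidean NN, ties broken by the lowest target index.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

namespace {

struct Node {
  int point = -1;   // index into target rows
  int axis = -1;
  int left = -1, right = -1;
};

struct KdTree {
  const double* pts; // column-major M x 3
  int m;
  std::vector<Node> nodes;
  int root = -1;

  double coord(int i, int axis) const { return pts[axis * m + i]; }

  int build(std::vector<int>& idx, int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int axis = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, axis), cb = coord(b, axis);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    int id = (int)nodes.size();
    nodes.push_back(Node());
    nodes[id].point = idx[mid];
    nodes[id].axis = axis;
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid + 1, hi, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  void search(int node, const double* q, int& best, double& bestd) const {
    if (node < 0) return;
    const Node& nd = nodes[node];
    int i = nd.point;
    double dx = q[0] - coord(i, 0);
    double dy = q[1] - coord(i, 1);
    double dz = q[2] - coord(i, 2);
    double d = dx * dx + dy * dy + dz * dz;
    if (d < bestd || (d == bestd && i < best)) { bestd = d; best = i; }
    double diff = q[nd.axis] - coord(i, nd.axis);
    int near = diff < 0 ? nd.left : nd.right;
    int far = diff < 0 ? nd.right : nd.left;
    search(near, q, best, bestd);
    if (diff * diff <= bestd) search(far, q, best, bestd);
  }
};

} // namespace

// [[Rcpp::export(name = ".nn_kdtree")]]
Rcpp::List nn_kdtree(Rcpp::NumericMatrix source, Rcpp::NumericMatrix target) {
  if (source.ncol() != 3 || target.ncol() != 3)
    Rcpp::stop("point matrices must have 3 columns");
  int n = source.nrow(), m = target.nrow();
  if (n == 0 || m == 0) Rcpp::stop("input error: empty point cloud");

  KdTree tree;
  tree.pts = target.begin();
  tree.m = m;
  tree.nodes.reserve(m);
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  tree.root = tree.build(idx, 0, m, 0);

  Rcpp::IntegerVector out_idx(n);
  Rcpp::NumericVector out_dist(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = { source(i, 0), source(i, 1), source(i, 2) };
    int best = m; // larger than any valid index so ties prefer real indices
    double bestd = R_PosInf;
    tree.search(tree.root, q, best, bestd);
    out_idx[i] = best + 1; // 1-based for R
    out_dist[i] = std::sqrt(bestd);
  }
  return Rcpp::List::create(Rcpp::Named("index") = out_idx,
                            Rcpp::Named("distance") = out_dist);
}
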