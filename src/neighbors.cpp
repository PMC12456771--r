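// Exact 3D kd-tree for k-nearest-neighbour and fixed-radius queries.
// Used by the SOR filter, normal/curvature estimation, FPFH neighbourhoods
// and stem labeling; all distances are Euclidean, results 1-based for R.
#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct KDTree {
  const double *x, *y, *z;
  int n;
  std::vector<int> idx;     // permutation of 0..n-1
  // node layout: recursive median split stored implicitly via ranges
  struct Node { int lo, hi, axis, left, right; double split; };
  std::vector<Node> nodes;

  double coord(int i, int ax) const {
    return ax == 0 ? x[i] : (ax == 1 ? y[i] : z[i]);
  }

  int build(int lo, int hi) {
    Node nd;
    nd.lo = lo; nd.hi = hi; nd.left = -1; nd.right = -1;
    nd.axis = -1; nd.split = 0.0;
    int me = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= 16) return me;  // leaf bucket
    double mn[3], mx[3];
    for (int a = 0; a < 3; ++a) { mn[a] = R_PosInf; mx[a] = R_NegInf; }
    for (int i = lo; i < hi; ++i)
      for (int a = 0; a < 3; ++a) {
        double v = coord(idx[i], a);
        if (v < mn[a]) mn[a] = v;
        if (v > mx[a]) mx[a] = v;
      }
    int axis = 0; double best = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > best) { best = mx[a] - mn[a]; axis = a; }
    if (best <= 0) return me;  // all points identical -> leaf
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, axis) < coord(b, axis); });
    nodes[me].axis = axis;
    nodes[me].split = coord(idx[mid], axis);
    int l = build(lo, mid);
    nodes[me].left = l;
    int r = build(mid, hi);
    nodes[me].right = r;
    return me;
  }

  void init(const NumericMatrix &pts) {
    n = pts.nrow();
    x = &pts(0, 0); y = &pts(0, 1); z = &pts(0, 2);
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(2 * n / 8 + 4);
    build(0, n);
  }

  double dist2(int i, double qx, double qy, double qz) const {
    double dx = x[i] - qx, dy = y[i] - qy, dz = z[i] - qz;
    return dx * dx + dy * dy + dz * dz;
  }

  // k nearest neighbours via bounded depth-first search with max-heap
  typedef std::pair<double, int> HeapEl;
  void knn_rec(int node, double qx, double qy, double qz, int k,
               std::priority_queue<HeapEl> &heap) const {
    const Node &nd = nodes[node];
    if (nd.axis < 0) {  // leaf
      for (int i = nd.lo; i < nd.hi; ++i) {
        double d2 = dist2(idx[i], qx, qy, qz);
        if ((int)heap.size() < k) heap.push(HeapEl(d2, idx[i]));
        else if (d2 < heap.top().first) { heap.pop(); heap.push(HeapEl(d2, idx[i])); }
      }
      return;
    }
    double q = nd.axis == 0 ? qx : (nd.axis == 1 ? qy : qz);
    int first = q < nd.split ? nd.left : nd.right;
    int second = q < nd.split ? nd.right : nd.left;
    knn_rec(first, qx, qy, qz, k, heap);
    double gap = q - nd.split;
    if ((int)heap.size() < k || gap * gap < heap.top().first)
      knn_rec(second, qx, qy, qz, k, heap);
  }

  void radius_rec(int node, double qx, double qy, double qz, double r2,
                  std::vector<int> &out) const {
    const Node &nd = nodes[node];
    if (nd.axis < 0) {
      for (int i = nd.lo; i < nd.hi; ++i)
        if (dist2(idx[i], qx, qy, qz) <= r2) out.push_back(idx[i]);
      return;
    }
    double q = nd.axis == 0 ? qx : (nd.axis == 1 ? qy : qz);
    double gap = q - nd.split;
    int first = q < nd.split ? nd.left : nd.right;
    int second = q < nd.split ? nd.right : nd.left;
    radius_rec(first, qx, qy, qz, r2, out);
    if (gap * gap <= r2) radius_rec(second, qx, qy, qz, r2, out);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_knn(NumericMatrix data, NumericMatrix query, int k) {
  if (data.ncol() != 3 || query.ncol() != 3)
    stop("point matrices must have 3 columns");
  int n = data.nrow(), m = query.nrow();
  if (k < 1 || k > n) stop("k must be in [1, nrow(data)]");
  KDTree tree;
  tree.init(data);
  IntegerMatrix nn(m, k);
  NumericMatrix dd(m, k);
  for (int j = 0; j < m; ++j) {
    std::priority_queue<KDTree::HeapEl> heap;
    tree.knn_rec(0, query(j, 0), query(j, 1), query(j, 2), k, heap);
    int pos = (int)heap.size() - 1;
    while (!heap.empty()) {
      nn(j, pos) = heap.top().second + 1;
      dd(j, pos) = std::sqrt(heap.top().first);
      heap.pop();
      --pos;
    }
  }
  return List::create(_["index"] = nn, _["dist"] = dd);
}

// [[Rcpp::export]]
List cpp_radius(NumericMatrix data, NumericMatrix query, double radius) {
  if (data.ncol() != 3 || query.ncol() != 3)
    stop("point matrices must have 3 columns");
  if (radius <= 0) stop("radius must be positive");
  int m = query.nrow();
  KDTree tree;
  tree.init(data);
  List out(m);
  double r2 = radius * radius;
  std::vector<int> buf;
  for (int j = 0; j < m; ++j) {
    buf.clear();
    tree.radius_rec(0, query(j, 0), query(j, 1), query(j, 2), r2, buf);
    IntegerVector v(buf.size());
    for (size_t i = 0; i < buf.size(); ++i) v[i] = buf[i] + 1;
    out[j] = v;
  }
  return out;
}

// Exact distance from each point to the nearest segment of an ordered
// polyline, with kd-tree pruning over the polyline vertices. `step` is an
// upper bound on consecutive vertex spacing, used to bound the candidate set.
// [[Rcpp::export]]
NumericVector cpp_polyline_dist(NumericMatrix points, NumericMatrix poly,
                                double radius, double step) {
  int n = points.nrow(), m = poly.nrow();
  if (m < 1) stop("empty polyline");
  KDTree tree;
  tree.init(poly);
  NumericVector out(n);
  double bound = radius + step;  // beyond this we only need "far" (=Inf)
  double b2 = bound * bound;
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    buf.clear();
    tree.radius_rec(0, px, py, pz, b2, buf);
    if (buf.empty()) { out[i] = R_PosInf; continue; }
    double best = R_PosInf;
    for (size_t t = 0; t < buf.size(); ++t) {
      int j = buf[t];  // 0-based vertex; check segments [j-1,j] and [j,j+1]
      for (int s = j - 1; s <= j; ++s) {
        if (s < 0 || s + 1 >= m) {
          if (s == j - 1 && j == 0) {  // endpoint as degenerate segment
            double d2 = tree.dist2(0, px, py, pz);
            if (d2 < best) best = d2;
          }
          continue;
        }
        double ax = poly(s, 0), ay = poly(s, 1), az = poly(s, 2);
        double bx = poly(s + 1, 0), by = poly(s + 1, 1), bz = poly(s + 1, 2);
        double vx = bx - ax, vy = by - ay, vz = bz - az;
        double wx = px - ax, wy = py - ay, wz = pz - az;
        double vv = vx * vx + vy * vy + vz * vz;
        double tpar = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
        if (tpar < 0) tpar = 0;
        if (tpar > 1) tpar = 1;
        double dx = wx - tpar * vx, dy = wy - tpar * vy, dz = wz - tpar * vz;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
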