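#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Median-split kd-tree over 3D points, stored implicitly in a permutation
// array (node = middle element of its range). Ties in query distance are
// broken toward the lowest point index so results are deterministic.

namespace {

struct KDTree {
  std::vector<double> pts;  // row-major x,y,z per point
  std::vector<int> perm;
  int n;

  void init(const NumericMatrix &m) {
    n = m.nrow();
    pts.resize(3 * (size_t)n);
    for (int i = 0; i < n; ++i) {
      pts[3 * (size_t)i]     = m(i, 0);
      pts[3 * (size_t)i + 1] = m(i, 1);
      pts[3 * (size_t)i + 2] = m(i, 2);
    }
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    build(0, n, 0);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    const double *p = pts.data();
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [p, ax](int a, int b) {
                       double va = p[3 * (size_t)a + ax], vb = p[3 * (size_t)b + ax];
                       if (va != vb) return va < vb;
                       return a < b;
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  inline double dist2(const double *q, int i) const {
    double dx = q[0] - pts[3 * (size_t)i];
    double dy = q[1] - pts[3 * (size_t)i + 1];
    double dz = q[2] - pts[3 * (size_t)i + 2];
    return dx * dx + dy * dy + dz * dz;
  }

  void nn(int lo, int hi, int depth, const double *q, double &bd2, int &bi) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = perm[mid];
    double d2 = dist2(q, p);
    if (d2 < bd2 || (d2 == bd2 && p < bi)) { bd2 = d2; bi = p; }
    int ax = depth % 3;
    double diff = q[ax] - pts[3 * (size_t)p + ax];
    if (diff <= 0) {
      nn(lo, mid, depth + 1, q, bd2, bi);
      if (diff * diff <= bd2) nn(mid + 1, hi, depth + 1, q, bd2, bi);
    } else {
      nn(mid + 1, hi, depth + 1, q, bd2, bi);
      if (diff * diff <= bd2) nn(lo, mid, depth + 1, q, bd2, bi);
    }
  }

  // k nearest via bounded max-"heap" kept as a sorted vector (k is small).
  void knn(int lo, int hi, int depth, const double *q, int k,
           std::vector<std::pair<double, int> > &best) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = perm[mid];
    double d2 = dist2(q, p);
    std::pair<double, int> cand(d2, p);
    if ((int)best.size() < k) {
      best.insert(std::upper_bound(best.begin(), best.end(), cand), cand);
    } else if (cand < best.back()) {
      best.pop_back();
      best.insert(std::upper_bound(best.begin(), best.end(), cand), cand);
    }
    int ax = depth % 3;
    double diff = q[ax] - pts[3 * (size_t)p + ax];
    double bound = ((int)best.size() < k) ? R_PosInf : best.back().first;
    if (diff <= 0) {
      knn(lo, mid, depth + 1, q, k, best);
      bound = ((int)best.size() < k) ? R_PosInf : best.back().first;
      if (diff * diff <= bound) knn(mid + 1, hi, depth + 1, q, k, best);
    } else {
      knn(mid + 1, hi, depth + 1, q, k, best);
      bound = ((int)best.size() < k) ? R_PosInf : best.back().first;
      if (diff * diff <= bound) knn(lo, mid, depth + 1, q, k, best);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_nearest(NumericMatrix reference, NumericMatrix query) {
  KDTree tree;
  tree.init(reference);
  int m = query.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  double q[3];
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    double bd2 = R_PosInf;
    int bi = -1;
    tree.nn(0, tree.n, 0, q, bd2, bi);
    idx[i] = bi + 1;  // 1-based
    dist[i] = std::sqrt(bd2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// [[Rcpp::export]]
List cpp_knearest(NumericMatrix reference, NumericMatrix query, int k) {
  KDTree tree;
  tree.init(reference);
  int m = query.nrow();
  if (k > tree.n) k = tree.n;
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  double q[3];
  std::vector<std::pair<double, int> > best;
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    best.clear();
    tree.knn(0, tree.n, 0, q, k, best);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = best[j].second + 1;
      dist(i, j) = std::sqrt(best[j].first);
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
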