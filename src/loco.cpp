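#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Time-scaled distance between points i and j:
//   sqrt(dx^2 + dy^2 + (svt * dt)^2), svt = s * v_char (m/s), dt in seconds.
static inline double tsd(double dx, double dy, double dt, double svt) {
  double tt = svt * dt;
  return std::sqrt(dx * dx + dy * dy + tt * tt);
}

// Adaptive nearest-neighbour selection: for each parent, neighbours sorted
// by TSD are accumulated while the running TSD sum stays <= a. The parent
// itself (TSD 0) is always a member. Returns a list of 1-based index vectors.
// [[Rcpp::export]]
List cpp_adaptive_nn(NumericVector x, NumericVector y, NumericVector t,
                     double svt, double a) {
  int n = x.size();
  List out(n);
  std::vector<std::pair<double, int> > d;
  d.reserve(n);
  for (int i = 0; i < n; ++i) {
    d.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dij = tsd(x[j] - x[i], y[j] - y[i], t[j] - t[i], svt);
      if (dij <= a) d.push_back(std::make_pair(dij, j));
    }
    std::sort(d.begin(), d.end());
    std::vector<int> mem;
    mem.push_back(i + 1);
    double acc = 0.0;
    for (size_t k = 0; k < d.size(); ++k) {
      acc += d[k].first;
      if (acc > a) break;
      mem.push_back(d[k].second + 1);
    }
    std::sort(mem.begin(), mem.end());
    out[i] = IntegerVector(mem.begin(), mem.end());
  }
  return out;
}

// For each parent, the cumulative TSD of its k nearest neighbours: the
// smallest a-value for which that parent would keep >= k neighbours.
// [[Rcpp::export]]
NumericVector cpp_a_for_k(NumericVector x, NumericVector y, NumericVector t,
                          double svt, int k) {
  int n = x.size();
  NumericVector out(n);
  std::vector<double> d;
  d.reserve(n);
  for (int i = 0; i < n; ++i) {
    d.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      d.push_back(tsd(x[j] - x[i], y[j] - y[i], t[j] - t[i], svt));
    }
    int kk = std::min<int>(k, (int)d.size());
    if (kk == 0) { out[i] = 0.0; continue; }
    std::partial_sort(d.begin(), d.begin() + kk, d.end());
    double acc = 0.0;
    for (int m = 0; m < kk; ++m) acc += d[m];
    out[i] = acc;
  }
  return out;
}

// Classic density-based spatial clustering (DBSCAN). Returns 0 for noise,
// 1..k for cluster membership.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, double eps,
                         int min_pts) {
  int n = x.size();
  double eps2 = eps * eps;
  IntegerVector cl(n, 0);
  std::vector<bool> visited(n, false);
  std::vector<int> neigh, seeds;
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    neigh.clear();
    for (int j = 0; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy <= eps2) neigh.push_back(j);
    }
    if ((int)neigh.size() < min_pts) continue;  // noise (may be claimed later)
    ++k;
    cl[i] = k;
    seeds = neigh;
    for (size_t s = 0; s < seeds.size(); ++s) {
      int q = seeds[s];
      if (cl[q] == 0) cl[q] = k;  // border point
      if (visited[q]) continue;
      visited[q] = true;
      std::vector<int> nq;
      for (int j = 0; j < n; ++j) {
        double dx = x[j] - x[q], dy = y[j] - y[q];
        if (dx * dx + dy * dy <= eps2) nq.push_back(j);
      }
      if ((int)nq.size() >= min_pts)
        for (size_t m = 0; m < nq.size(); ++m) seeds.push_back(nq[m]);
    }
  }
  return cl;
}
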