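#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include "neighbors.h"
using namespace Rcpp;

// Two independent implementations of the accessible distance transform on
// the discrete voxel graph, used as oracles for the join-tree route.

// Widest-path (maximum bottleneck) multi-source Dijkstra: the value at x is
// the maximum over paths from any seed of the minimum EDT along the path,
// endpoints included. Unreachable void stays 0.

// [[Rcpp::export]]
NumericVector cpp_widest_path(NumericVector edt, IntegerVector dims,
                              IntegerVector seeds, int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  Offsets off = make_offsets(connectivity);
  const int no = (int)off.di.size();
  NumericVector val(n);
  std::priority_queue<std::pair<double, R_xlen_t> > pq;
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t v = seeds[s] - 1;
    double e = edt[v];
    if (e > 0.0 && e > val[v]) {
      val[v] = e;
      pq.push(std::make_pair(e, v));
    }
  }
  while (!pq.empty()) {
    double d = pq.top().first;
    R_xlen_t x = pq.top().second;
    pq.pop();
    if (d < val[x]) continue;
    int i = (int)(x % n1);
    int j = (int)((x / n1) % n2);
    int k = (int)(x / ((R_xlen_t)n1 * n2));
    for (int q = 0; q < no; ++q) {
      int ii = i + off.di[q], jj = j + off.dj[q], kk = k + off.dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
        continue;
      R_xlen_t y = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
      if (edt[y] <= 0.0) continue;
      double cand = std::min(d, (double)edt[y]);
      if (cand > val[y]) {
        val[y] = cand;
        pq.push(std::make_pair(cand, y));
      }
    }
  }
  return val;
}

// Literal threshold-sweep flood fill: for every distinct positive EDT value
// t in descending order, flood the superlevel set {EDT >= t} from the seeds
// and stamp still-unassigned reached voxels with t.

// [[Rcpp::export]]
NumericVector cpp_flood_sweep(NumericVector edt, IntegerVector dims,
                              IntegerVector seeds, int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  Offsets off = make_offsets(connectivity);
  const int no = (int)off.di.size();

  std::vector<double> thr;
  R_xlen_t nvoid = 0;
  for (R_xlen_t s = 0; s < n; ++s)
    if (edt[s] > 0.0) { thr.push_back(edt[s]); ++nvoid; }
  std::sort(thr.begin(), thr.end(), std::greater<double>());
  thr.erase(std::unique(thr.begin(), thr.end()), thr.end());

  NumericVector res(n);
  std::vector<int> visited(n, 0);
  std::vector<R_xlen_t> stack;
  int gen = 0;
  R_xlen_t remaining = nvoid;
  for (size_t ti = 0; ti < thr.size() && remaining > 0; ++ti) {
    double t = thr[ti];
    ++gen;
    stack.clear();
    for (int s = 0; s < seeds.size(); ++s) {
      R_xlen_t v = seeds[s] - 1;
      if (edt[v] >= t && visited[v] != gen) {
        visited[v] = gen;
        stack.push_back(v);
      }
    }
    while (!stack.empty()) {
      R_xlen_t x = stack.back();
      stack.pop_back();
      if (res[x] == 0.0) { res[x] = t; --remaining; }
      int i = (int)(x % n1);
      int j = (int)((x / n1) % n2);
      int k = (int)(x / ((R_xlen_t)n1 * n2));
      for (int q = 0; q < no; ++q) {
        int ii = i + off.di[q], jj = j + off.dj[q], kk = k + off.dk[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
          continue;
        R_xlen_t y = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (edt[y] >= t && visited[y] != gen) {
          visited[y] = gen;
          stack.push_back(y);
        }
      }
    }
  }
  return res;
}
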