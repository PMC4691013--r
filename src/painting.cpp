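#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Maximal-sphere painting: out(y) = max{ D(x) : |y - x| <= D(x) } over
// centres x, distances between voxel centres in voxel units. The inclusive
// comparison is evaluated on squared distances with a small absolute slack;
// since squared centre-to-centre distances are integers and D^2 is (up to
// floating error) an integer for distance-transform input, the test is exact.

static const double SLACK = 1e-7;

// [[Rcpp::export]]
NumericVector cpp_paint(NumericVector rvox, IntegerVector dims,
                        LogicalVector use) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const bool restrict_centres = use.size() == n;
  NumericVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) {
    double r = rvox[s];
    if (r <= 0.0) continue;
    if (restrict_centres && !use[s]) continue;
    int i = (int)(s % n1);
    int j = (int)((s / n1) % n2);
    int k = (int)(s / ((R_xlen_t)n1 * n2));
    double r2 = r * r + SLACK;
    int ri = (int)std::floor(r + 1e-9);
    int i0 = std::max(0, i - ri), i1 = std::min(n1 - 1, i + ri);
    int j0 = std::max(0, j - ri), j1 = std::min(n2 - 1, j + ri);
    int k0 = std::max(0, k - ri), k1 = std::min(n3 - 1, k + ri);
    for (int kk = k0; kk <= k1; ++kk) {
      double dk2 = (double)(kk - k) * (kk - k);
      for (int jj = j0; jj <= j1; ++jj) {
        double dj2 = (double)(jj - j) * (jj - j);
        if (dk2 + dj2 > r2) continue;
        R_xlen_t base = (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        for (int ii = i0; ii <= i1; ++ii) {
          double d2 = dk2 + dj2 + (double)(ii - i) * (ii - i);
          if (d2 <= r2 && out[base + ii] < r) out[base + ii] = r;
        }
      }
    }
  }
  return out;
}

// A centre x is redundant when some other centre x' carries a sphere that
// contains x's sphere: D(x') >= D(x) + |x - x'|. The scan allows ties
// (boundary-touching containment) via a tiny tolerance; ties are broken
// toward keeping the larger-D centre, and among equals the earlier voxel
// in column-major order, so at least one member of a mutually-containing
// pair survives.

// [[Rcpp::export]]
LogicalVector cpp_nonredundant(NumericVector rvox, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector keep(n);
  std::vector<R_xlen_t> centres;
  for (R_xlen_t s = 0; s < n; ++s)
    if (rvox[s] > 0.0) centres.push_back(s);
  const R_xlen_t m = (R_xlen_t)centres.size();
  std::vector<int> ci(m), cj(m), ck(m);
  for (R_xlen_t a = 0; a < m; ++a) {
    R_xlen_t s = centres[a];
    ci[a] = (int)(s % n1);
    cj[a] = (int)((s / n1) % n2);
    ck[a] = (int)(s / ((R_xlen_t)n1 * n2));
  }
  for (R_xlen_t a = 0; a < m; ++a) {
    double ra = rvox[centres[a]];
    bool redundant = false;
    for (R_xlen_t b = 0; b < m && !redundant; ++b) {
      if (b == a) continue;
      double rb = rvox[centres[b]];
      if (rb < ra) continue;
      double gap = rb - ra;             // need |x-x'| <= gap (up to ties)
      double di = ci[b] - ci[a], dj = cj[b] - cj[a], dk = ck[b] - ck[a];
      double d2 = di * di + dj * dj + dk * dk;
      if (d2 > (gap + 1e-9) * (gap + 1e-9)) continue;
      if (rb > ra || (rb == ra && centres[b] < centres[a]))
        redundant = true;
    }
    if (!redundant) keep[centres[a]] = true;
  }
  return keep;
}
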