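#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact squared Euclidean distance transform on an isotropic voxel grid,
// computed separably with the lower-envelope-of-parabolas method.
// Distances are between voxel centres, in voxel units; the result is an
// exact integer (stored as double) for binary input.

static const double BIG = 1e20;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector biomass, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = biomass[t] ? 0.0 : BIG;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (i, stride 1)
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k2 = 0; k2 < n2; ++k2) {
      R_xlen_t base = (R_xlen_t)n1 * (k2 + (R_xlen_t)n2 * k3);
      for (int q = 0; q < n1; ++q) f[q] = out[base + q];
      dt1d(f, d, v, z, n1);
      for (int q = 0; q < n1; ++q) out[base + q] = d[q];
    }
  // axis 2 (j, stride n1)
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k1 = 0; k1 < n1; ++k1) {
      R_xlen_t base = k1 + (R_xlen_t)n1 * n2 * k3;
      for (int q = 0; q < n2; ++q) f[q] = out[base + (R_xlen_t)n1 * q];
      dt1d(f, d, v, z, n2);
      for (int q = 0; q < n2; ++q) out[base + (R_xlen_t)n1 * q] = d[q];
    }
  // axis 3 (k, stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int k2 = 0; k2 < n2; ++k2)
    for (int k1 = 0; k1 < n1; ++k1) {
      R_xlen_t base = k1 + (R_xlen_t)n1 * k2;
      for (int q = 0; q < n3; ++q) f[q] = out[base + s3 * q];
      dt1d(f, d, v, z, n3);
      for (int q = 0; q < n3; ++q) out[base + s3 * q] = d[q];
    }
  // snap to exact integers (values are sums of integer squares)
  for (R_xlen_t t = 0; t < n; ++t)
    if (out[t] < BIG / 2) out[t] = std::floor(out[t] + 0.5);
  return out;
}
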