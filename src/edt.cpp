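#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact 1D squared distance transform under sampled parabolas
// (Felzenszwalb & Huttenlocher). f is the squared-distance function along
// one line, step is the physical sample spacing (mm) along that line.
static void dt1d(std::vector<double>& f, double step) {
  const int n = (int)f.size();
  static const double INF = std::numeric_limits<double>::infinity();
  const double s2 = step * step;

  int first = -1;
  for (int i = 0; i < n; ++i)
    if (f[i] < INF) { first = i; break; }
  if (first < 0) return; // no finite source on this line

  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);

  int k = 0;
  v[0] = first;
  z[0] = -INF;
  z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
               (2.0 * s2 * (q - v[k]));
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }

  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + f[v[k]];
  }
  f.swap(d);
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector feature, IntegerVector dims,
                    NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);

  // squared distance, 0 at feature voxels
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = feature[i] ? 0.0 : INF;

  std::vector<double> line;

  // pass along x (fastest-varying index)
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = out[base + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }

  // pass along y
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)y * nx];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = line[y];
    }

  // pass along z
  line.resize(nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = out[base + (R_xlen_t)z * nxy];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = line[z];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::sqrt(out[i]);
  return out;
}
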