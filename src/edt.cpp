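#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher 2012), tolerating +Inf entries.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> idx;
  idx.reserve(n);
  for (int q = 0; q < n; q++)
    if (f[q] < INF) idx.push_back(q);
  if (idx.empty()) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  std::vector<int> v(idx.size());
  std::vector<double> z(idx.size() + 1);
  int k = 0;
  v[0] = idx[0];
  z[0] = -INF;
  z[1] = INF;
  for (size_t m = 1; m < idx.size(); m++) {
    int q = idx[m];
    double s;
    while (true) { // z[0] = -Inf guarantees termination with k >= 0
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * (q - p));
      if (s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in voxel units) from every voxel to the nearest
// TRUE voxel of a 3D logical array, via three separable 1D passes on squared
// distances. TRUE voxels get distance 0; an all-FALSE mask yields +Inf.
// [[Rcpp::export]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);

  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;

  // pass along x (fastest-varying)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }

  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
    }

  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * nx * ny] = d[z];
    }

  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
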