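#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 3D voxel kernels shared by the mask builders and biomarker extractors.
// All arrays are passed as flat vectors in R's column-major layout with an
// explicit dim triple; spacing is mm per axis.

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  const int noff = offsets.nrow();
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[idx]) continue;
        for (int k = 0; k < noff; ++k) {
          const int xx = x + offsets(k, 0);
          const int yy = y + offsets(k, 1);
          const int zz = z + offsets(k, 2);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          out[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] = true;
        }
      }
    }
  }
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope)
// in physical coordinates x_q = sp * q; parabolas with infinite offset are
// skipped so all-background lines propagate Inf.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zbuf,
                 int n, double sp) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    const double xq = sp * q, fq = f[q];
    double s = 0.0;
    while (k >= 0) {
      const int p = v[k];
      const double xp = sp * p;
      s = ((fq + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= zbuf[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = (k == 0) ? -INF : s;
    zbuf[k + 1] = INF;
  }
  if (k < 0) {             // no finite parabola on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = sp * q;
    while (zbuf[j + 1] < xq) ++j;
    const double diff = xq - sp * v[j];
    d[q] = diff * diff + f[v[j]];
  }
}

// Exact anisotropic squared Euclidean distance (mm^2) from every voxel to the
// nearest feature voxel (mask == TRUE). Voxels with no feature anywhere get Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // x-axis
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, v, zbuf, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // y-axis
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = x + (R_xlen_t)nx * ny * (R_xlen_t)z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, v, zbuf, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // z-axis
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = out[base + plane * z];
      dt1d(f, d, v, zbuf, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + plane * z] = d[z];
    }
  return out;
}

// Connected-component labeling of a binary volume, 26- or 6-connectivity.
// Labels are 1..K in first-encounter order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int noff = (int)dxs.size();

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    labels[start] = ++next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t idx = stack.back();
      stack.pop_back();
      const int x = (int)(idx % nx);
      const int y = (int)((idx / nx) % ny);
      const int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (int k = 0; k < noff; ++k) {
        const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}
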