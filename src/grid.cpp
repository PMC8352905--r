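#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sample a 3D column-major array at continuous 0-based voxel coordinates.
// Points outside [0, dim-1] on any axis get `fill`.
// [[Rcpp::export]]
NumericVector c_sample_trilinear(NumericVector data, IntegerVector dim,
                                 NumericVector xi, NumericVector yi, NumericVector zi,
                                 double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  const double *d = data.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = xi[p], y = yi[p], z = zi[p];
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[p] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    const double c000 = d[x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0)];
    const double c100 = d[x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0)];
    const double c010 = d[x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0)];
    const double c110 = d[x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0)];
    const double c001 = d[x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1)];
    const double c101 = d[x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1)];
    const double c011 = d[x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1)];
    const double c111 = d[x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1)];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector c_sample_nearest(NumericVector data, IntegerVector dim,
                               NumericVector xi, NumericVector yi, NumericVector zi,
                               double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  const double *d = data.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = xi[p], y = yi[p], z = zi[p];
    long ix = std::lround(x), iy = std::lround(y), iz = std::lround(z);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
      out[p] = fill;
    } else {
      out[p] = d[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
    }
  }
  return out;
}

// Label connected components of a binary 3D array (column-major).
// connectivity: 6, 18 or 26. Returns integer array, 0 = background,
// components numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerVector c_label_components(IntegerVector mask, IntegerVector dim,
                                 int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2)) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nnb = (int)dx.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cx = (int)(cur % nx);
      R_xlen_t rest = cur / nx;
      int cy = (int)(rest % ny);
      int cz = (int)(rest / ny);
      for (int k = 0; k < nnb; ++k) {
        int qx = cx + dx[k], qy = cy + dy[k], qz = cz + dz[k];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz) continue;
        R_xlen_t q = qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
        if (mask[q] != 0 && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = next;
  return lab;
}
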