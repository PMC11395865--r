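#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Resample a 3D volume onto an output grid through a 4x4 voxel-to-voxel
// affine map M: continuous 0-based source index = M %*% (i, j, k, 1) for
// 0-based output index (i, j, k). method 0 = nearest neighbour,
// 1 = trilinear. Voxels mapping outside the source grid (or touching NA
// neighbours under trilinear) receive `fill`.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector srcdim,
                                  IntegerVector outdim, NumericMatrix M,
                                  int method, double fill) {
  const int nx = srcdim[0], ny = srcdim[1], nz = srcdim[2];
  const int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *s = src.begin();
  double *o = out.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      const double xj = m01 * j + m03, yj = m11 * j + m13, zj = m21 * j + m23;
      const double xk = m02 * k, yk = m12 * k, zk = m22 * k;
      for (int i = 0; i < ox; ++i, ++idx) {
        const double x = m00 * i + xj + xk;
        const double y = m10 * i + yj + yk;
        const double z = m20 * i + zj + zk;
        if (method == 0) {
          const int xi = (int)std::lround(x), yi = (int)std::lround(y),
                    zi = (int)std::lround(z);
          if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz) {
            o[idx] = fill;
          } else {
            o[idx] = s[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
          }
        } else {
          const double xf = std::floor(x), yf = std::floor(y), zf = std::floor(z);
          const int x0 = (int)xf, y0 = (int)yf, z0 = (int)zf;
          if (x0 < 0 || x0 + 1 >= nx || y0 < 0 || y0 + 1 >= ny ||
              z0 < 0 || z0 + 1 >= nz) {
            // allow exact upper boundary
            if (x >= 0 && x <= nx - 1 && y >= 0 && y <= ny - 1 &&
                z >= 0 && z <= nz - 1) {
              const int xi = (int)std::lround(x), yi = (int)std::lround(y),
                        zi = (int)std::lround(z);
              o[idx] = s[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
            } else {
              o[idx] = fill;
            }
            continue;
          }
          const double dx = x - xf, dy = y - yf, dz = z - zf;
          const R_xlen_t b = (R_xlen_t)x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
          const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
          const double c000 = s[b],            c100 = s[b + sx];
          const double c010 = s[b + sy],       c110 = s[b + sx + sy];
          const double c001 = s[b + sz],       c101 = s[b + sx + sz];
          const double c011 = s[b + sy + sz],  c111 = s[b + sx + sy + sz];
          if (ISNAN(c000) || ISNAN(c100) || ISNAN(c010) || ISNAN(c110) ||
              ISNAN(c001) || ISNAN(c101) || ISNAN(c011) || ISNAN(c111)) {
            o[idx] = fill;
            continue;
          }
          const double c00 = c000 * (1 - dx) + c100 * dx;
          const double c10 = c010 * (1 - dx) + c110 * dx;
          const double c01 = c001 * (1 - dx) + c101 * dx;
          const double c11 = c011 * (1 - dx) + c111 * dx;
          const double c0 = c00 * (1 - dy) + c10 * dy;
          const double c1 = c01 * (1 - dy) + c11 * dy;
          o[idx] = c0 * (1 - dz) + c1 * dz;
        }
      }
    }
  }
  return out;
}

// 26-connected component labelling of a binary 3D mask.
// Returns integer labels, 0 for background, components numbered from 1
// in scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int *m = mask.begin();
  int *L = lab.begin();
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (m[start] != TRUE || L[start] != 0) continue;
    ++next;
    L[start] = next;
    q.push(start);
    while (!q.empty()) {
      const R_xlen_t v = q.front(); q.pop();
      const int z = (int)(v / ((R_xlen_t)nx * ny));
      const int rem = (int)(v - (R_xlen_t)z * nx * ny);
      const int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            const R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (m[w] == TRUE && L[w] == 0) {
              L[w] = next;
              q.push(w);
            }
          }
        }
      }
    }
  }
  lab.attr("ncomp") = next;
  return lab;
}

static void gauss_kernel(double sigma, std::vector<double> &k) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  k.assign(2 * r + 1, 0.0);
  double sum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    sum += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= sum;
}

// Separable Gaussian smoothing of a 3D volume with reflected boundaries.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector src, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> k;
  gauss_kernel(sigma, k);
  const int r = ((int)k.size() - 1) / 2;
  NumericVector a(clone(src)), b(n);
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  const int sizes[3] = {nx, ny, nz};
  double *pa = a.begin(), *pb = b.begin();
  for (int axis = 0; axis < 3; ++axis) {
    const R_xlen_t st = strides[axis];
    const int sz = sizes[axis];
    for (R_xlen_t base = 0; base < n; ++base) {
      // position along axis for this linear index
      const int pos = (int)((base / st) % sz);
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int p = pos + t;
        if (p < 0) p = -p;                       // reflect
        if (p >= sz) p = 2 * sz - 2 - p;
        acc += k[t + r] * pa[base + (R_xlen_t)(p - pos) * st];
      }
      pb[base] = acc;
    }
    std::swap(pa, pb);
  }
  if (pa == a.begin()) return a;
  return b;
}
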