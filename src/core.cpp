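// Low-level voxel-grid kernels. All 3D arrays arrive as R arrays in
// column-major order with dimensions (nx, ny, nz); x is the fastest index.
// Physical coordinates: voxel (i,j,k) (1-based in R) has its center at
// origin + (c(i,j,k) - 0.5) * spacing.
#include <Rcpp.h>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), separable,
// with per-axis physical spacing. Input f: squared distances (0 at sources,
// INF elsewhere). Transformed in place axis by axis.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s2) {
  // s2 = spacing^2 for this axis
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double sq = (f[q] + s2 * q * q);
    double sv = (f[v[k]] + s2 * v[k] * v[k]);
    double denom = 2.0 * s2 * (q - v[k]);
    double s = (sq - sv) / denom;
    while (s <= z[k]) {
      --k;
      sv = (f[v[k]] + s2 * v[k] * v[k]);
      denom = 2.0 * s2 * (q - v[k]);
      s = (sq - sv) / denom;
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
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector source, IntegerVector dims,
                      NumericVector spacing) {
  // Distance (um) from every voxel center to the nearest voxel center where
  // source == TRUE. Returns Inf when no source voxel exists.
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite stand-in for "no source yet": infinities break the
  // parabola intersection arithmetic (inf - inf)
  double big = 4.0 * (nx * spacing[0] * nx * spacing[0] +
                      ny * spacing[1] * ny * spacing[1] +
                      nz * spacing[2] * nz * spacing[2]);
  std::vector<double> g(n);
  for (R_xlen_t t = 0; t < n; ++t) g[t] = source[t] ? 0.0 : big;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  double s2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nx, s2);
      for (int i = 0; i < nx; ++i) g[idx3(i, j, k, nx, ny)] = d[i];
    }
  // y pass
  s2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, ny, s2);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j];
    }
  // z pass
  s2 = spacing[2] * spacing[2];
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nz, s2);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t)
    out[t] = (g[t] >= big) ? R_PosInf : std::sqrt(g[t]);
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_chamfer(LogicalVector mask, IntegerVector dims,
                          double spacing) {
  // <3,4,5> chamfer distance (um) from foreground voxels to the nearest
  // background voxel, two-pass; requires isotropic spacing. Background = 0.
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  for (R_xlen_t t = 0; t < n; ++t) d[t] = mask[t] ? INF : 0.0;
  // <3,4,5>/3 metric has direction-dependent ratio to Euclidean in
  // [4/(3*sqrt(2)), sqrt(11)/3] ~ [0.9428, 1.1055]; rescaling by
  // 2/(min+max) centers the band at +/-7.94% (the documented 8% bound)
  const double rescale =
      2.0 / (4.0 / (3.0 * std::sqrt(2.0)) + std::sqrt(11.0) / 3.0);
  const double unit = spacing / 3.0 * rescale;

  // offsets with negative lexicographic order for the forward pass
  struct Off { int di, dj, dk; double w; };
  std::vector<Off> fwd;
  for (int dk = -1; dk <= 0; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        double w = (m == 1 ? 3.0 : (m == 2 ? 4.0 : 5.0)) * unit;
        fwd.push_back({di, dj, dk, w});
      }

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        if (d[t] == 0.0) continue;
        double best = d[t];
        for (const Off& o : fwd) {
          int ii = i + o.di, jj = j + o.dj, kk = k + o.dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          double cand = d[idx3(ii, jj, kk, nx, ny)] + o.w;
          if (cand < best) best = cand;
        }
        d[t] = best;
      }
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        if (d[t] == 0.0) continue;
        double best = d[t];
        for (const Off& o : fwd) {
          int ii = i - o.di, jj = j - o.dj, kk = k - o.dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          double cand = d[idx3(ii, jj, kk, nx, ny)] + o.w;
          if (cand < best) best = cand;
        }
        d[t] = best;
      }

  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = d[t];
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_geodesic(LogicalVector mask, IntegerVector dims,
                           NumericVector spacing, int seed0,
                           int connectivity) {
  // Dijkstra shortest within-mask path length (um) from the seed voxel
  // (0-based linear index) to every foreground voxel. Edge weight = Euclidean
  // distance between voxel centers; 6- or 26-connectivity.
  // Background voxels -> NA; unreachable foreground -> Inf.
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (seed0 < 0 || seed0 >= n || !mask[seed0])
    stop("seed voxel must be a foreground voxel");

  struct Off { int di, dj, dk; double w; };
  std::vector<Off> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        double w = std::sqrt(di * di * spacing[0] * spacing[0] +
                             dj * dj * spacing[1] * spacing[1] +
                             dk * dk * spacing[2] * spacing[2]);
        offs.push_back({di, dj, dk, w});
      }

  std::vector<double> dist(n, INF);
  dist[seed0] = 0.0;
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  pq.push({0.0, seed0});
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double dcur = top.first;
    int t = top.second;
    if (dcur > dist[t]) continue;
    int k = t / (nx * ny);
    int rem = t - k * nx * ny;
    int j = rem / nx;
    int i = rem - j * nx;
    for (const Off& o : offs) {
      int ii = i + o.di, jj = j + o.dj, kk = k + o.dk;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int u = idx3(ii, jj, kk, nx, ny);
      if (!mask[u]) continue;
      double cand = dcur + o.w;
      if (cand < dist[u]) {
        dist[u] = cand;
        pq.push({cand, u});
      }
    }
  }

  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t)
    out[t] = mask[t] ? dist[t] : NA_REAL;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with reflective boundaries; sigma in voxels.
static void blur1d(std::vector<double>& a, std::vector<double>& tmp,
                   const std::vector<double>& kern, int n) {
  int r = (int)kern.size() / 2;
  for (int q = 0; q < n; ++q) {
    double acc = 0.0;
    for (int t = -r; t <= r; ++t) {
      int p = q + t;
      if (p < 0) p = -p - 1;
      if (p >= n) p = 2 * n - p - 1;
      acc += a[p] * kern[t + r];
    }
    tmp[q] = acc;
  }
  for (int q = 0; q < n; ++q) a[q] = tmp[q];
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector arr, IntegerVector dims,
                                NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(arr.begin(), arr.end());
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), tmp(nmax);

  if (sigma_vox[0] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[0]);
    for (int kk = 0; kk < nz; ++kk)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) line[i] = g[idx3(i, j, kk, nx, ny)];
        blur1d(line, tmp, k, nx);
        for (int i = 0; i < nx; ++i) g[idx3(i, j, kk, nx, ny)] = line[i];
      }
  }
  if (sigma_vox[1] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[1]);
    for (int kk = 0; kk < nz; ++kk)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) line[j] = g[idx3(i, j, kk, nx, ny)];
        blur1d(line, tmp, k, ny);
        for (int j = 0; j < ny; ++j) g[idx3(i, j, kk, nx, ny)] = line[j];
      }
  }
  if (nz > 1 && sigma_vox[2] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[2]);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int kk = 0; kk < nz; ++kk) line[kk] = g[idx3(i, j, kk, nx, ny)];
        blur1d(line, tmp, k, nz);
        for (int kk = 0; kk < nz; ++kk) g[idx3(i, j, kk, nx, ny)] = line[kk];
      }
  }
  NumericVector out(n);
  std::copy(g.begin(), g.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector arr, IntegerVector dims,
                            NumericVector spacing) {
  // Second-difference Laplacian with per-axis physical spacing (um^-2 units),
  // replicated boundary.
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double wx = 1.0 / (spacing[0] * spacing[0]);
  double wy = 1.0 / (spacing[1] * spacing[1]);
  double wz = 1.0 / (spacing[2] * spacing[2]);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        double c = arr[t];
        double xm = arr[idx3(std::max(i - 1, 0), j, k, nx, ny)];
        double xp = arr[idx3(std::min(i + 1, nx - 1), j, k, nx, ny)];
        double ym = arr[idx3(i, std::max(j - 1, 0), k, nx, ny)];
        double yp = arr[idx3(i, std::min(j + 1, ny - 1), k, nx, ny)];
        double acc = (xm + xp - 2 * c) * wx + (ym + yp - 2 * c) * wy;
        if (nz > 1) {
          double zm = arr[idx3(i, j, std::max(k - 1, 0), nx, ny)];
          double zp = arr[idx3(i, j, std::min(k + 1, nz - 1), nx, ny)];
          acc += (zm + zp - 2 * c) * wz;
        }
        out[t] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector arr, IntegerVector dims,
                               double min_value) {
  // 1-based linear indices of voxels >= all 26-neighbours and > min_value.
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> hits;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        double c = arr[t];
        if (!(c > min_value)) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1 && ismax; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 ||
                  ii >= nx || jj >= ny || kk >= nz) continue;
              if (arr[idx3(ii, jj, kk, nx, ny)] > c) ismax = false;
            }
        if (ismax) hits.push_back((int)t + 1);
      }
  return wrap(hits);
}

// [[Rcpp::export]]
NumericVector cpp_render_gaussians(IntegerVector dims, NumericVector spacing,
                                   NumericVector origin, NumericMatrix pos,
                                   NumericVector amplitude, double sigma_um) {
  // Sum of isotropic (in um) Gaussian blobs sampled on an anisotropic grid.
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double reach = 4.0 * sigma_um;
  double inv2s2 = 1.0 / (2.0 * sigma_um * sigma_um);
  for (int p = 0; p < pos.nrow(); ++p) {
    double cx = pos(p, 0), cy = pos(p, 1), cz = pos(p, 2);
    int i0 = std::max(0, (int)std::floor((cx - reach - origin[0]) / spacing[0] - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + reach - origin[0]) / spacing[0] - 0.5));
    int j0 = std::max(0, (int)std::floor((cy - reach - origin[1]) / spacing[1] - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + reach - origin[1]) / spacing[1] - 0.5));
    int k0 = std::max(0, (int)std::floor((cz - reach - origin[2]) / spacing[2] - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil((cz + reach - origin[2]) / spacing[2] - 0.5));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + (k + 0.5) * spacing[2] - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + (j + 0.5) * spacing[1] - cy;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + (i + 0.5) * spacing[0] - cx;
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 > reach * reach) continue;
          out[idx3(i, j, k, nx, ny)] += amplitude[p] * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  // Trilinear interpolation at physical points. Corners that are NA (outside
  // a mask) or non-finite are dropped and weights renormalized; if every
  // corner is unusable, returns NA. Points outside the grid -> NA.
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double gx = (pts(p, 0) - origin[0]) / spacing[0] - 0.5;
    double gy = (pts(p, 1) - origin[1]) / spacing[1] - 0.5;
    double gz = (pts(p, 2) - origin[2]) / spacing[2] - 0.5;
    if (gx < -0.5 || gy < -0.5 || gz < -0.5 ||
        gx > nx - 0.5 || gy > ny - 0.5 || gz > nz - 0.5) {
      out[p] = NA_REAL;
      continue;
    }
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0.0, wsum = 0.0;
    bool any = false;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
          if (ii < 0 || jj < 0 || kk < 0 ||
              ii >= nx || jj >= ny || kk >= nz) continue;
          double v = arr[idx3(ii, jj, kk, nx, ny)];
          if (ISNAN(v)) continue;
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (w <= 0) continue;
          acc += w * v;
          wsum += w;
          any = true;
        }
    out[p] = (any && wsum > 0) ? acc / wsum : NA_REAL;
  }
  return out;
}
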