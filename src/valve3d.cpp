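#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3D connected component labelling. Components are labelled 1..K in
// raster-scan (column-major linear index) order of each component's first
// voxel, found by breadth-first search under 6- or 26-adjacency.
// [[Rcpp::export]]
IntegerVector label_cc_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nn = (int)dx.size();

  std::vector<R_xlen_t> queue;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      R_xlen_t p = queue.back();
      queue.pop_back();
      int z = (int)(p / ((R_xlen_t)nx * ny));
      int rem = (int)(p - (R_xlen_t)z * nx * ny);
      int y = rem / nx;
      int x = rem % nx;
      for (int k = 0; k < nn; ++k) {
        int x2 = x + dx[k], y2 = y + dy[k], z2 = z + dz[k];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
        R_xlen_t q = (R_xlen_t)z2 * nx * ny + (R_xlen_t)y2 * nx + x2;
        if (mask[q] && labels[q] == 0) {
          labels[q] = next_label;
          queue.push_back(q);
        }
      }
    }
  }
  return labels;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), f and d of length n, strides handled by caller.
static void dt1d(const double *f, double *d, int *v, double *zbuf, int n) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -1e30;
  zbuf[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    int p = v[k];
    d[q] = (double)(q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (voxel units) from each foreground voxel to
// the nearest background voxel centre; everything outside the array is
// background, handled exactly by the axis-aligned distance to the nearest
// out-of-array voxel centre.
// [[Rcpp::export]]
NumericVector edt_sq_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f.data(), dd.data(), v.data(), zbuf.data(), nx);
      for (int x = 0; x < nx; ++x) d[base + x] = dd[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)y * nx];
      dt1d(f.data(), dd.data(), v.data(), zbuf.data(), ny);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = dd[y];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = d[base + (R_xlen_t)z * nxy];
      dt1d(f.data(), dd.data(), v.data(), zbuf.data(), nz);
      for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)z * nxy] = dd[z];
    }

  // array border: nearest outside voxel centre is axis-aligned
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
        if (d[i] == 0.0) continue;
        int b = std::min(std::min(x + 1, nx - x), std::min(std::min(y + 1, ny - y), std::min(z + 1, nz - z)));
        double b2 = (double)b * b;
        if (b2 < d[i]) d[i] = b2;
      }
  return d;
}

// Local thickness by sphere propagation: every non-redundant foreground
// voxel q paints the value 2*(EDT(q) - 0.5) into all voxels p with
// |p - q| <= EDT(q). A centre is redundant when its sphere is contained in
// a 26-neighbour's sphere (|q-n| + EDT(q) <= EDT(n)), which preserves the
// result exactly. Painting proceeds from the largest spheres down.
// [[Rcpp::export]]
NumericVector thickness_paint_3d(LogicalVector mask, NumericVector edt, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  NumericVector th(n, 0.0);

  // neighbour offsets with distances, for the redundancy test
  std::vector<int> ndx, ndy, ndz;
  std::vector<double> ndist;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        ndx.push_back(a); ndy.push_back(b); ndz.push_back(c);
        ndist.push_back(std::sqrt((double)(a * a + b * b + c * c)));
      }

  std::vector<R_xlen_t> centres;
  centres.reserve(1024);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
        if (!mask[i]) continue;
        double r = edt[i];
        bool redundant = false;
        for (size_t k = 0; k < ndx.size(); ++k) {
          int x2 = x + ndx[k], y2 = y + ndy[k], z2 = z + ndz[k];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
          R_xlen_t q = (R_xlen_t)z2 * nxy + (R_xlen_t)y2 * nx + x2;
          if (mask[q] && edt[q] >= r + ndist[k]) { redundant = true; break; }
        }
        if (!redundant) centres.push_back(i);
      }

  std::sort(centres.begin(), centres.end(),
            [&](R_xlen_t a, R_xlen_t b) { return edt[a] > edt[b]; });

  // Painting proceeds from the largest sphere down, so the final value of a
  // voxel is the value of the first sphere covering it. Each x-run of a
  // sphere is filled with first-writer-wins semantics through path-halving
  // jump pointers (nxt[i] = next not-yet-painted voxel at or after i),
  // which makes repeated overlap of equal spheres on ridge plateaus cheap.
  std::vector<R_xlen_t> nxt(n + 1);
  for (R_xlen_t i = 0; i <= n; ++i) nxt[i] = i;
  auto find_unset = [&](R_xlen_t i) {
    while (nxt[i] != i) {
      nxt[i] = nxt[nxt[i]];
      i = nxt[i];
    }
    return i;
  };

  for (R_xlen_t c : centres) {
    double r = edt[c];
    double val = 2.0 * (r - 0.5);
    // squared EDT values are integers; recover them exactly after the sqrt
    double r2 = std::round(r * r);
    int ri = (int)std::floor(r);
    int z = (int)(c / nxy);
    int rem = (int)(c - (R_xlen_t)z * nxy);
    int y = rem / nx;
    int x = rem % nx;
    int z0 = std::max(0, z - ri), z1 = std::min(nz - 1, z + ri);
    int y0 = std::max(0, y - ri), y1 = std::min(ny - 1, y + ri);
    for (int zz = z0; zz <= z1; ++zz) {
      double dz2 = (double)(zz - z) * (zz - z);
      for (int yy = y0; yy <= y1; ++yy) {
        double dyz2 = dz2 + (double)(yy - y) * (yy - y);
        if (dyz2 > r2) continue;
        int rx = (int)std::floor(std::sqrt(r2 - dyz2));
        while ((double)(rx + 1) * (rx + 1) <= r2 - dyz2) ++rx;
        while (rx > 0 && (double)rx * rx > r2 - dyz2) --rx;
        int x0 = std::max(0, x - rx), x1 = std::min(nx - 1, x + rx);
        R_xlen_t base = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx;
        R_xlen_t a = base + x0, b = base + x1;
        R_xlen_t i = find_unset(a);
        while (i <= b) {
          th[i] = val;
          nxt[i] = i + 1;
          i = find_unset(i + 1);
        }
      }
    }
  }
  // only mask voxels carry thickness
  for (R_xlen_t i = 0; i < n; ++i) if (!mask[i]) th[i] = 0.0;
  return th;
}

// Shift-based binary morphology: dilation (OR over shifts by +offsets) or
// erosion (AND over shifts by -offsets) of a 3D mask by an offset list.
// [[Rcpp::export]]
LogicalVector morph_3d(LogicalVector mask, IntegerVector dims,
                       IntegerMatrix offsets, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  const int no = offsets.nrow();
  LogicalVector out(n, dilate ? FALSE : TRUE);
  for (int k = 0; k < no; ++k) {
    int dx = offsets(k, 0), dy = offsets(k, 1), dz = offsets(k, 2);
    if (!dilate) { dx = -dx; dy = -dy; dz = -dz; }
    int x0 = std::max(0, dx), x1 = std::min(nx, nx + dx);
    int y0 = std::max(0, dy), y1 = std::min(ny, ny + dy);
    int z0 = std::max(0, dz), z1 = std::min(nz, nz + dz);
    if (dilate) {
      for (int z = z0; z < z1; ++z)
        for (int y = y0; y < y1; ++y) {
          R_xlen_t dst = (R_xlen_t)z * nxy + (R_xlen_t)y * nx;
          R_xlen_t src = (R_xlen_t)(z - dz) * nxy + (R_xlen_t)(y - dy) * nx - dx;
          for (int x = x0; x < x1; ++x)
            if (mask[src + x]) out[dst + x] = TRUE;
        }
    } else {
      // erosion: out(p) requires p + offset inside and set; shifting by the
      // negated offset, voxels whose source falls outside the array fail.
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          R_xlen_t dst = (R_xlen_t)z * nxy + (R_xlen_t)y * nx;
          bool zy_ok = (z >= z0 && z < z1 && y >= y0 && y < y1);
          R_xlen_t src = (R_xlen_t)(z - dz) * nxy + (R_xlen_t)(y - dy) * nx - dx;
          for (int x = 0; x < nx; ++x) {
            bool ok = zy_ok && x >= x0 && x < x1 && mask[src + x];
            if (!ok) out[dst + x] = FALSE;
          }
        }
    }
  }
  return out;
}
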