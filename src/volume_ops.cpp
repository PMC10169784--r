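#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact Euclidean distance transform (separable lower-envelope scan) ----
// 1D squared-distance transform with sample spacing h.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double diff = qq - (double)v[k] * h;
    d[q] = diff * diff + f[v[k]];
  }
}

// Distance (mm) from every voxel to the nearest background (zero) voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dims,
                      NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  const double INF = 1e20;
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, spacing[0], nx);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, spacing[1], ny);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, spacing[2], nz);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = std::sqrt(d[z]);
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}

// ---- 3x3x3 all-ones neighbourhood sum (zero padding) ----
// [[Rcpp::export]]
IntegerVector cpp_boxsum27(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int s = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx; if (xx < 0 || xx >= nx) continue;
              s += mask[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
            }
          }
        }
        out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = s;
      }
  out.attr("dim") = dims;
  return out;
}

// ---- connected-component labelling (conn = 6 or 26) ----
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && ad != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---- count of in-mask 26-neighbours per voxel ----
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(IntegerVector mask, IntegerVector dims) {
  IntegerVector s = cpp_boxsum27(mask, dims);
  R_xlen_t n = s.size();
  for (R_xlen_t i = 0; i < n; ++i) s[i] -= mask[i];
  return s;
}

// ---- simultaneous competitive label growth restricted to a mask ----
// labels: 0 = unclaimed; growth into voxels where allowed != 0.
// Each iteration every unclaimed allowed voxel with >= 1 labelled neighbour
// (of `connectivity`) takes the label with the most adjacent claimed voxels,
// ties to the lowest label code.  max_iter < 0 grows until stable.
// [[Rcpp::export]]
IntegerVector cpp_competitive_grow(IntegerVector labels, IntegerVector allowed,
                                   IntegerVector dims, int max_iter,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector cur = clone(labels);
  int maxlab = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (cur[i] > maxlab) maxlab = cur[i];
  std::vector<int> cnt(maxlab + 1);
  int iter = 0;
  while (max_iter < 0 || iter < max_iter) {
    ++iter;
    std::vector<R_xlen_t> idx;
    std::vector<int> newlab;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t v = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
          if (cur[v] || !allowed[v]) continue;
          std::fill(cnt.begin(), cnt.end(), 0);
          bool any = false;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (connectivity == 6 && ad != 1) continue;
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz) continue;
                int l = cur[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
                if (l > 0) { cnt[l]++; any = true; }
              }
          if (!any) continue;
          int best = 0, bestc = 0;
          for (int l = 1; l <= maxlab; ++l)
            if (cnt[l] > bestc) { bestc = cnt[l]; best = l; }
          idx.push_back(v);
          newlab.push_back(best);
        }
    if (idx.empty()) break;
    for (size_t i = 0; i < idx.size(); ++i) cur[idx[i]] = newlab[i];
  }
  cur.attr("dim") = dims;
  return cur;
}

// ---- nearest reference point (1-based index) for each query point ----
// [[Rcpp::export]]
IntegerVector cpp_nearest_point(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j + 1; }
    }
    out[i] = bj;
  }
  return out;
}

// ---- resampling (cell-centred alignment) ----
// mode 0 = nearest, 1 = trilinear
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, IntegerVector dims,
                             IntegerVector out_dims, int mode) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  double sx = (double)nx / ox, sy = (double)ny / oy, sz = (double)nz / oz;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double fx = (x + 0.5) * sx - 0.5;
        double fy = (y + 0.5) * sy - 0.5;
        double fz = (z + 0.5) * sz - 0.5;
        R_xlen_t o = (R_xlen_t)z * ox * oy + (R_xlen_t)y * ox + x;
        if (mode == 0) {
          int ix = std::min(nx - 1, std::max(0, (int)std::lround(fx)));
          int iy = std::min(ny - 1, std::max(0, (int)std::lround(fy)));
          int iz = std::min(nz - 1, std::max(0, (int)std::lround(fz)));
          out[o] = vol[(R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix];
        } else {
          int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
              z0 = (int)std::floor(fz);
          double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          double acc = 0.0;
          for (int c = 0; c < 8; ++c) {
            int xx = x0 + (c & 1), yy = y0 + ((c >> 1) & 1),
                zz = z0 + ((c >> 2) & 1);
            double w = ((c & 1) ? tx : 1 - tx) * (((c >> 1) & 1) ? ty : 1 - ty) *
                       (((c >> 2) & 1) ? tz : 1 - tz);
            xx = std::min(nx - 1, std::max(0, xx));
            yy = std::min(ny - 1, std::max(0, yy));
            zz = std::min(nz - 1, std::max(0, zz));
            acc += w * vol[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
          }
          out[o] = acc;
        }
      }
  out.attr("dim") = out_dims;
  return out;
}

// ---- label-aware downsampling: per-cell majority, background loses ties ----
// Output voxel (x,y,z) covers input cells [floor(x*sx), floor((x+1)*sx)).
// [[Rcpp::export]]
IntegerVector cpp_majority_downsample(IntegerVector lab, IntegerVector dims,
                                      IntegerVector out_dims, int ncodes) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  IntegerVector out((R_xlen_t)ox * oy * oz);
  double sx = (double)nx / ox, sy = (double)ny / oy, sz = (double)nz / oz;
  std::vector<int> cnt(ncodes + 1);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        int x0 = (int)std::floor(x * sx), x1 = (int)std::floor((x + 1) * sx);
        int y0 = (int)std::floor(y * sy), y1 = (int)std::floor((y + 1) * sy);
        int z0 = (int)std::floor(z * sz), z1 = (int)std::floor((z + 1) * sz);
        if (x1 <= x0) x1 = x0 + 1;
        if (y1 <= y0) y1 = y0 + 1;
        if (z1 <= z0) z1 = z0 + 1;
        x1 = std::min(x1, nx); y1 = std::min(y1, ny); z1 = std::min(z1, nz);
        std::fill(cnt.begin(), cnt.end(), 0);
        for (int zz = z0; zz < z1; ++zz)
          for (int yy = y0; yy < y1; ++yy)
            for (int xx = x0; xx < x1; ++xx) {
              int l = lab[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
              if (l >= 0 && l <= ncodes) cnt[l]++;
            }
        // majority among foreground; background wins only by strict majority
        int best = 0, bestc = 0;
        for (int l = 1; l <= ncodes; ++l)
          if (cnt[l] > bestc) { bestc = cnt[l]; best = l; }
        if (cnt[0] > bestc) best = 0;
        out[(R_xlen_t)z * ox * oy + (R_xlen_t)y * ox + x] = best;
      }
  out.attr("dim") = out_dims;
  return out;
}

// ---- separable 3x3x3 all-ones convolution on a real field (zero padding) ----
// [[Rcpp::export]]
NumericVector cpp_boxblur3(NumericVector f, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> tmp(n);
  // x pass
  for (R_xlen_t base = 0; base < n; base += nx) {
    for (int x = 0; x < nx; ++x) {
      double s = f[base + x];
      if (x > 0) s += f[base + x - 1];
      if (x < nx - 1) s += f[base + x + 1];
      tmp[base + x] = s;
    }
  }
  // y pass
  std::vector<double> tmp2(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t row = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      R_xlen_t up = row - nx, dn = row + nx;
      for (int x = 0; x < nx; ++x) {
        double s = tmp[row + x];
        if (y > 0) s += tmp[up + x];
        if (y < ny - 1) s += tmp[dn + x];
        tmp2[row + x] = s;
      }
    }
  // z pass
  R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    R_xlen_t row = (R_xlen_t)z * plane;
    for (R_xlen_t i = 0; i < plane; ++i) {
      double s = tmp2[row + i];
      if (z > 0) s += tmp2[row - plane + i];
      if (z < nz - 1) s += tmp2[row + plane + i];
      out[row + i] = s;
    }
  }
  out.attr("dim") = dims;
  return out;
}
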