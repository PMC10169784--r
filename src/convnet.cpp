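#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Minimal native 3D convolution stack used by the small U-nets.
// Tensor layout: column-major R arrays with dim (X, Y, Z, C).
// Kernels: dim (KX, KY, KZ, Cin, Cout), odd extents, "same" zero padding.
// Convolutions run as per-z-slice im2col + BLAS dgemm: the kernel array is
// already the (KX*KY*KZ*Cin) x Cout matrix dgemm needs, and for a fixed z
// the (x, y) voxels of a slice are contiguous rows of the output.
// 2D networks use KZ = 1 and z pooling factor 1.

static inline R_xlen_t off4(int x, int y, int z, int c, int nx, int ny, int nz) {
  return ((R_xlen_t)c * nz + z) * ny * nx + (R_xlen_t)y * nx + x;
}

// fill the im2col matrix (nx*ny rows, kx*ky*kz*ci cols) for output slice z
static void im2col_slice(const double *X, int nx, int ny, int nz, int ci,
                         int kx, int ky, int kz, int z, double *col) {
  int px = kx / 2, py = ky / 2, pz = kz / 2;
  R_xlen_t rows = (R_xlen_t)nx * ny;
  R_xlen_t c = 0;
  for (int ic = 0; ic < ci; ++ic)
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx, ++c) {
          double *dst = col + c * rows;
          int sz = z + dz - pz, sy = dy - py, sx = dx - px;
          if (sz < 0 || sz >= nz) {
            std::memset(dst, 0, sizeof(double) * rows);
            continue;
          }
          int x0 = std::max(0, -sx), x1 = std::min(nx, nx - sx);
          for (int y = 0; y < ny; ++y) {
            int ys = y + sy;
            double *d = dst + (R_xlen_t)y * nx;
            if (ys < 0 || ys >= ny || x1 <= x0) {
              std::memset(d, 0, sizeof(double) * nx);
              continue;
            }
            if (x0 > 0) std::memset(d, 0, sizeof(double) * x0);
            std::memcpy(d + x0, X + off4(x0 + sx, ys, sz, ic, nx, ny, nz),
                        sizeof(double) * (x1 - x0));
            if (x1 < nx) std::memset(d + x1, 0, sizeof(double) * (nx - x1));
          }
        }
}

// scatter-add a (nx*ny) x (kx*ky*kz*ci) column matrix back into dx at slice z
static void col2im_slice(const double *col, int nx, int ny, int nz, int ci,
                         int kx, int ky, int kz, int z, double *DX) {
  int px = kx / 2, py = ky / 2, pz = kz / 2;
  R_xlen_t rows = (R_xlen_t)nx * ny;
  R_xlen_t c = 0;
  for (int ic = 0; ic < ci; ++ic)
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx, ++c) {
          const double *src = col + c * rows;
          int sz = z + dz - pz, sy = dy - py, sx = dx - px;
          if (sz < 0 || sz >= nz) continue;
          int x0 = std::max(0, -sx), x1 = std::min(nx, nx - sx);
          for (int y = 0; y < ny; ++y) {
            int ys = y + sy;
            if (ys < 0 || ys >= ny || x1 <= x0) continue;
            const double *s = src + (R_xlen_t)y * nx + x0;
            double *d = DX + off4(x0 + sx, ys, sz, ic, nx, ny, nz);
            for (int x = x0; x < x1; ++x) *d++ += *s++;
          }
        }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias) {
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  NumericVector y((R_xlen_t)nx * ny * nz * co);
  const double *X = x.begin(), *W = w.begin();
  double *Y = y.begin();
  int rows = nx * ny, K = kx * ky * kz * ci;
  std::vector<double> col((R_xlen_t)rows * K);
  const double one = 1.0, zero = 0.0;
  for (int z = 0; z < nz; ++z) {
    im2col_slice(X, nx, ny, nz, ci, kx, ky, kz, z, col.data());
    double *Yz = Y + (R_xlen_t)z * rows;
    int ldc = nx * ny * nz;
    F77_CALL(dgemm)("N", "N", &rows, &co, &K, &one, col.data(), &rows,
                    const_cast<double *>(W), &K, &zero, Yz, &ldc
                    FCONE FCONE);
  }
  for (int oc = 0; oc < co; ++oc) {
    double b = bias[oc];
    double *Yc = Y + (R_xlen_t)oc * nx * ny * nz;
    for (R_xlen_t i = 0; i < (R_xlen_t)nx * ny * nz; ++i) Yc[i] += b;
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, co);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xd, NumericVector w,
                    IntegerVector wd, NumericVector dy) {
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  NumericVector dx_(x.size()), dw(w.size()), db(co);
  const double *X = x.begin(), *W = w.begin(), *DY = dy.begin();
  double *DX = dx_.begin(), *DW = dw.begin();
  int rows = nx * ny, K = kx * ky * kz * ci;
  std::vector<double> col((R_xlen_t)rows * K);
  std::vector<double> dcol((R_xlen_t)rows * K);
  const double one = 1.0, zero = 0.0;
  int ldy = nx * ny * nz;
  for (int z = 0; z < nz; ++z) {
    const double *DYz = DY + (R_xlen_t)z * rows;
    im2col_slice(X, nx, ny, nz, ci, kx, ky, kz, z, col.data());
    // dW += col^T %*% dy_slice
    F77_CALL(dgemm)("T", "N", &K, &co, &rows, &one, col.data(), &rows,
                    const_cast<double *>(DYz), &ldy, &one, DW, &K
                    FCONE FCONE);
    // dcol = dy_slice %*% W^T
    F77_CALL(dgemm)("N", "T", &rows, &K, &co, &one,
                    const_cast<double *>(DYz), &ldy,
                    const_cast<double *>(W), &K, &zero, dcol.data(), &rows
                    FCONE FCONE);
    col2im_slice(dcol.data(), nx, ny, nz, ci, kx, ky, kz, z, DX);
  }
  for (int oc = 0; oc < co; ++oc) {
    double acc = 0.0;
    const double *dyp = DY + (R_xlen_t)oc * nx * ny * nz;
    for (R_xlen_t i = 0; i < (R_xlen_t)nx * ny * nz; ++i) acc += dyp[i];
    db[oc] = acc;
  }
  dx_.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx_, _["dw"] = dw, _["db"] = db);
}

// max pooling by integer factors (fx, fy, fz); returns pooled values and
// 1-based argmax indices into the input
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xd, IntegerVector f) {
  int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx / fx, oy = ny / fy, oz = nz / fz;
  NumericVector y((R_xlen_t)ox * oy * oz * nc);
  IntegerVector idx(y.size());
  const double *X = x.begin();
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx) {
          double best = -1e300;
          R_xlen_t bi = 0;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                R_xlen_t ii = off4(xx * fx + dx, yy * fy + dy, z * fz + dz, c,
                                   nx, ny, nz);
                if (X[ii] > best) { best = X[ii]; bi = ii; }
              }
          R_xlen_t oo = ((R_xlen_t)c * oz + z) * oy * ox + (R_xlen_t)yy * ox + xx;
          y[oo] = best;
          idx[oo] = (int)(bi + 1);
        }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              IntegerVector xd) {
  NumericVector dx_((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx_[idx[i] - 1] += dy[i];
  dx_.attr("dim") = xd;
  return dx_;
}

// nearest-neighbour upsampling by integer factors
// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector xd,
                               IntegerVector f) {
  int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx * fx, oy = ny * fy, oz = nz * fz;
  NumericVector y((R_xlen_t)ox * oy * oz * nc);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx)
          y[((R_xlen_t)c * oz + z) * oy * ox + (R_xlen_t)yy * ox + xx] =
              x[off4(xx / fx, yy / fy, z / fz, c, nx, ny, nz)];
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dy, IntegerVector yd,
                               IntegerVector f) {
  int ox = yd[0], oy = yd[1], oz = yd[2], nc = yd[3];
  int fx = f[0], fy = f[1], fz = f[2];
  int nx = ox / fx, ny = oy / fy, nz = oz / fz;
  NumericVector dx_((R_xlen_t)nx * ny * nz * nc);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx)
          dx_[off4(xx / fx, yy / fy, z / fz, c, nx, ny, nz)] +=
              dy[((R_xlen_t)c * oz + z) * oy * ox + (R_xlen_t)yy * ox + xx];
  dx_.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return dx_;
}

// instance norm forward: per-channel standardization + affine; returns z
// (pre-ReLU) along with xhat and sigma for the backward pass
// [[Rcpp::export]]
List cpp_instnorm_fwd(NumericVector y, IntegerVector yd, NumericVector gamma,
                      NumericVector beta, double eps) {
  int nc = yd[3];
  R_xlen_t nvox = (R_xlen_t)yd[0] * yd[1] * yd[2];
  NumericVector z(y.size()), xhat(y.size()), sg(nc);
  for (int c = 0; c < nc; ++c) {
    const double *yc = y.begin() + (R_xlen_t)c * nvox;
    double mu = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) mu += yc[i];
    mu /= nvox;
    double var = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      double d = yc[i] - mu;
      var += d * d;
    }
    double s = std::sqrt(var / nvox + eps);
    sg[c] = s;
    double g = gamma[c], b = beta[c];
    double *xh = xhat.begin() + (R_xlen_t)c * nvox;
    double *zc = z.begin() + (R_xlen_t)c * nvox;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      xh[i] = (yc[i] - mu) / s;
      zc[i] = g * xh[i] + b;
    }
  }
  z.attr("dim") = yd;
  xhat.attr("dim") = yd;
  return List::create(_["z"] = z, _["xhat"] = xhat, _["sg"] = sg);
}

// backward through ReLU (mask on z) and instance norm
// [[Rcpp::export]]
List cpp_instnorm_relu_bwd(NumericVector dy, NumericVector z,
                           NumericVector xhat, NumericVector sg,
                           NumericVector gamma, IntegerVector yd) {
  int nc = yd[3];
  R_xlen_t nvox = (R_xlen_t)yd[0] * yd[1] * yd[2];
  NumericVector dx(dy.size()), dgamma(nc), dbeta(nc);
  for (int c = 0; c < nc; ++c) {
    const double *dyc = dy.begin() + (R_xlen_t)c * nvox;
    const double *zc = z.begin() + (R_xlen_t)c * nvox;
    const double *xh = xhat.begin() + (R_xlen_t)c * nvox;
    double g = gamma[c], s = sg[c];
    double dgam = 0.0, dbet = 0.0, m1 = 0.0, m2 = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      double dz = (zc[i] > 0) ? dyc[i] : 0.0;
      dgam += dz * xh[i];
      dbet += dz;
      double dxh = dz * g;
      m1 += dxh;
      m2 += dxh * xh[i];
    }
    m1 /= nvox; m2 /= nvox;
    double *dxc = dx.begin() + (R_xlen_t)c * nvox;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      double dz = (zc[i] > 0) ? dyc[i] : 0.0;
      double dxh = dz * g;
      dxc[i] = (dxh - m1 - xh[i] * m2) / s;
    }
    dgamma[c] = dgam;
    dbeta[c] = dbet;
  }
  dx.attr("dim") = yd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
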