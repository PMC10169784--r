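#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Homotopic curve thinning with (26, 6) connectivity.
//
// A voxel is "simple" (deletable without changing topology) iff the object
// restricted to its 26-neighbourhood has exactly one 26-connected component,
// and the background restricted to its 18-neighbourhood has exactly one
// 6-connected component that is 6-adjacent to the voxel (Malandain-Bertrand
// characterisation).  Border voxels are deleted in increasing order of a
// priority field (here the distance transform), so the surviving skeleton
// rides the medial ridge; endpoints (<= 1 object 26-neighbour) are kept,
// which preserves curve extremities.

static const int N26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},
  {-1,1,-1},{0,1,-1},{1,1,-1},{-1,-1,0},{0,-1,0},{1,-1,0},
  {-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},{-1,-1,1},
  {0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};

// index into the 3x3x3 cube (0..26), centre = 13
static inline int cubeIdx(int dx, int dy, int dz) {
  return (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
}

// Fill nb[27] with object occupancy of the 3x3x3 cube around v.
static void fillCube(const std::vector<unsigned char> &obj, int nx, int ny,
                     int nz, int x, int y, int z, unsigned char nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        unsigned char val = 0;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          val = obj[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
        nb[cubeIdx(dx, dy, dz)] = val;
      }
}

static int countObjectNeighbors(const unsigned char nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++c;
  return c;
}

// number of 26-connected components of the object within N26 (centre excluded)
static int objectComponents26(const unsigned char nb[27]) {
  int lab[27];
  for (int i = 0; i < 27; ++i) lab[i] = 0;
  int ncomp = 0;
  int stack[27], top;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || lab[s]) continue;
    ++ncomp;
    top = 0; stack[top++] = s; lab[s] = ncomp;
    while (top) {
      int v = stack[--top];
      int vx = v % 3 - 1, vy = (v / 3) % 3 - 1, vz = v / 9 - 1;
      for (int k = 0; k < 26; ++k) {
        int wx = vx + N26[k][0], wy = vy + N26[k][1], wz = vz + N26[k][2];
        if (wx < -1 || wx > 1 || wy < -1 || wy > 1 || wz < -1 || wz > 1)
          continue;
        int w = cubeIdx(wx, wy, wz);
        if (w == 13 || !nb[w] || lab[w]) continue;
        lab[w] = ncomp;
        stack[top++] = w;
      }
    }
  }
  return ncomp;
}

// number of 6-connected components of the background within N18 that are
// 6-adjacent to the centre
static int backgroundComponents6(const unsigned char nb[27]) {
  // N18: cube positions with |dx|+|dy|+|dz| <= 2 (centre excluded)
  int lab[27];
  for (int i = 0; i < 27; ++i) lab[i] = 0;
  int ncomp = 0, adjComp = 0;
  int stack[27], top;
  for (int s = 0; s < 27; ++s) {
    if (s == 13) continue;
    int sx = s % 3 - 1, sy = (s / 3) % 3 - 1, sz = s / 9 - 1;
    int manh = std::abs(sx) + std::abs(sy) + std::abs(sz);
    if (manh > 2 || nb[s] || lab[s]) continue;
    ++ncomp;
    bool touches = false;
    top = 0; stack[top++] = s; lab[s] = ncomp;
    while (top) {
      int v = stack[--top];
      int vx = v % 3 - 1, vy = (v / 3) % 3 - 1, vz = v / 9 - 1;
      if (std::abs(vx) + std::abs(vy) + std::abs(vz) == 1) touches = true;
      static const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int wx = vx + F[k][0], wy = vy + F[k][1], wz = vz + F[k][2];
        if (wx < -1 || wx > 1 || wy < -1 || wy > 1 || wz < -1 || wz > 1)
          continue;
        if (std::abs(wx) + std::abs(wy) + std::abs(wz) > 2) continue;
        int w = cubeIdx(wx, wy, wz);
        if (w == 13 || nb[w] || lab[w]) continue;
        lab[w] = ncomp;
        stack[top++] = w;
      }
    }
    if (touches) ++adjComp;
  }
  return adjComp;  // only components 6-adjacent to the centre count
}

static bool isSimple(const std::vector<unsigned char> &obj, int nx, int ny,
                     int nz, int x, int y, int z) {
  unsigned char nb[27];
  fillCube(obj, nx, ny, nz, x, y, z, nb);
  if (objectComponents26(nb) != 1) return false;
  if (backgroundComponents6(nb) != 1) return false;
  return true;
}

static bool isEndpoint(const std::vector<unsigned char> &obj, int nx, int ny,
                       int nz, int x, int y, int z) {
  unsigned char nb[27];
  fillCube(obj, nx, ny, nz, x, y, z, nb);
  return countObjectNeighbors(nb) <= 1;
}

// [[Rcpp::export]]
IntegerVector cpp_thin(IntegerVector mask, IntegerVector dims,
                       NumericVector priority, NumericVector priority2) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<unsigned char> obj(n);
  for (size_t i = 0; i < n; ++i) obj[i] = mask[i] ? 1 : 0;

  struct Cand { double p; double p2; size_t idx; };
  bool changed = true;
  while (changed) {
    changed = false;
    std::vector<Cand> cands;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t v = (size_t)z * nx * ny + (size_t)y * nx + x;
          if (!obj[v]) continue;
          // border: at least one background 6-neighbour (incl. grid edge)
          bool border = false;
          static const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
          for (int k = 0; k < 6 && !border; ++k) {
            int xx = x + F[k][0], yy = y + F[k][1], zz = z + F[k][2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              border = true;
            else if (!obj[(size_t)zz * nx * ny + (size_t)yy * nx + xx])
              border = true;
          }
          if (!border) continue;
          if (isEndpoint(obj, nx, ny, nz, x, y, z)) continue;
          if (!isSimple(obj, nx, ny, nz, x, y, z)) continue;
          cands.push_back({priority[v], priority2[v], v});
        }
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Cand &a, const Cand &b) {
                       if (a.p != b.p) return a.p < b.p;
                       if (a.p2 != b.p2) return a.p2 < b.p2;
                       return a.idx < b.idx;
                     });
    for (const Cand &c : cands) {
      size_t v = c.idx;
      int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      if (isEndpoint(obj, nx, ny, nz, x, y, z)) continue;
      if (!isSimple(obj, nx, ny, nz, x, y, z)) continue;
      obj[v] = 0;
      changed = true;
    }
  }
  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = obj[i];
  out.attr("dim") = dims;
  return out;
}
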