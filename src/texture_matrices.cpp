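#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Gray-level matrix builders for 3D ROIs. The image comes in as a flattened
// integer array in column-major (R) order with 0 marking voxels outside the
// mask and 1..ng the discretized gray levels inside.

static const int NDIR = 13;
// unique 3D neighbour directions at Chebyshev distance 1 (26-neighbourhood / 2)
static const int DIRS[NDIR][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz;
}

// Symmetric co-occurrence counts, one ng*ng column per direction.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector disc, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng * ng, NDIR);
  for (int d = 0; d < NDIR; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int g1 = disc[idx3(x, y, z, nx, ny)];
          if (g1 == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          int g2 = disc[idx3(x2, y2, z2, nx, ny)];
          if (g2 == 0) continue;
          out((g1 - 1) + ng * (g2 - 1), d) += 1.0;
          out((g2 - 1) + ng * (g1 - 1), d) += 1.0;  // symmetrize
        }
  }
  return out;
}

// Run-length counts per direction: list of ng x maxRunLen matrices.
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector disc, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  List out(NDIR);
  for (int d = 0; d < NDIR; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    std::vector< std::vector<double> > counts(ng);  // counts[g][len-1]
    int maxlen = 1;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int g = disc[idx3(x, y, z, nx, ny)];
          if (g == 0) continue;
          // run start: predecessor along -d is outside grid/mask or differs
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inside(xp, yp, zp, nx, ny, nz) &&
              disc[idx3(xp, yp, zp, nx, ny)] == g) continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (inside(xn, yn, zn, nx, ny, nz) &&
                 disc[idx3(xn, yn, zn, nx, ny)] == g) {
            ++len; xn += dx; yn += dy; zn += dz;
          }
          if (len > maxlen) maxlen = len;
          if ((int)counts[g - 1].size() < len) counts[g - 1].resize(len, 0.0);
          counts[g - 1][len - 1] += 1.0;
        }
    NumericMatrix m(ng, maxlen);
    for (int g = 0; g < ng; ++g)
      for (int l = 0; l < (int)counts[g].size(); ++l)
        m(g, l) = counts[g][l];
    out[d] = m;
  }
  return out;
}

// Size-zone counts: connected components (26-connectivity) of equal gray
// level; returns ng x maxZoneSize matrix.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector disc, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector< std::vector<double> > counts(ng);
  int maxsize = 1;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    int g = disc[start];
    if (g == 0 || seen[start]) continue;
    int size = 0;
    seen[start] = 1;
    q.push(start);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
            int w = idx3(x2, y2, z2, nx, ny);
            if (!seen[w] && disc[w] == g) { seen[w] = 1; q.push(w); }
          }
    }
    if (size > maxsize) maxsize = size;
    if ((int)counts[g - 1].size() < size) counts[g - 1].resize(size, 0.0);
    counts[g - 1][size - 1] += 1.0;
  }
  NumericMatrix m(ng, maxsize);
  for (int g = 0; g < ng; ++g)
    for (int s = 0; s < (int)counts[g].size(); ++s)
      m(g, s) = counts[g][s];
  return m;
}

// Dependence counts (alpha = 0): for each masked voxel the number of
// 26-neighbours with the same gray level; returns ng x 27 matrix with
// column j holding dependence j-1.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector disc, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = disc[idx3(x, y, z, nx, ny)];
        if (g == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inside(x2, y2, z2, nx, ny, nz)) continue;
              if (disc[idx3(x2, y2, z2, nx, ny)] == g) ++dep;
            }
        m(g - 1, dep) += 1.0;
      }
  return m;
}

// Neighbourhood gray-tone difference: returns ng x 2 matrix of (n_i, s_i).
// Voxels with no masked neighbour do not contribute.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector disc, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = disc[idx3(x, y, z, nx, ny)];
        if (g == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inside(x2, y2, z2, nx, ny, nz)) continue;
              int g2 = disc[idx3(x2, y2, z2, nx, ny)];
              if (g2 > 0) { sum += g2; ++cnt; }
            }
        if (cnt == 0) continue;
        m(g - 1, 0) += 1.0;
        m(g - 1, 1) += std::fabs((double)g - sum / cnt);
      }
  return m;
}
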