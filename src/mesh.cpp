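#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marching-tetrahedra isosurface (level 0.5) of a scalar field, returning
// the total surface area and the enclosed volume of the closed triangle
// mesh. Each grid cell (cube of 8 voxel centres, with an implicit
// zero-padding layer around the grid) is split into 6 tetrahedra sharing
// the main diagonal; edge crossings are linearly interpolated. Opposite
// cube faces carry the same diagonal, so the mesh closes and the
// divergence-theorem volume is exact for the polyhedron.

struct Vec3 { double x, y, z; };

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.x - b.x, a.y - b.y, a.z - b.z}; return r;
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
  return r;
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
// linear interpolation of the 0.5 crossing along an edge
static inline Vec3 vcut(const Vec3 &a, double va, const Vec3 &b, double vb) {
  double t = (0.5 - va) / (vb - va);
  if (t < 0) t = 0; if (t > 1) t = 1;
  Vec3 r = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
            a.z + t * (b.z - a.z)};
  return r;
}

// accumulate one triangle, oriented so its normal points away from `ref`
static void add_tri(Vec3 a, Vec3 b, Vec3 c, const Vec3 &ref,
                    double &area, double &vol) {
  Vec3 n = vcross(vsub(b, a), vsub(c, a));
  Vec3 cen = {(a.x + b.x + c.x) / 3 - ref.x,
              (a.y + b.y + c.y) / 3 - ref.y,
              (a.z + b.z + c.z) / 3 - ref.z};
  if (vdot(n, cen) < 0) {
    Vec3 t = b; b = c; c = t;
    n = vcross(vsub(b, a), vsub(c, a));
  }
  area += std::sqrt(vdot(n, n)) / 2.0;
  vol += vdot(a, vcross(b, c)) / 6.0;  // signed, outward orientation
}

static void do_tet(const Vec3 p[4], const double v[4],
                   double &area, double &vol) {
  int in[4], ins[4], outs[4], ni = 0, no = 0;
  for (int k = 0; k < 4; ++k) {
    in[k] = v[k] > 0.5;
    if (in[k]) ins[ni++] = k; else outs[no++] = k;
  }
  if (ni == 0 || ni == 4) return;
  if (ni == 1 || ni == 3) {
    int a = (ni == 1) ? ins[0] : outs[0];
    Vec3 ref;  // centroid of the inside region of this tet
    if (ni == 1) ref = p[ins[0]];
    else {
      ref.x = (p[ins[0]].x + p[ins[1]].x + p[ins[2]].x) / 3;
      ref.y = (p[ins[0]].y + p[ins[1]].y + p[ins[2]].y) / 3;
      ref.z = (p[ins[0]].z + p[ins[1]].z + p[ins[2]].z) / 3;
    }
    Vec3 q[3]; int m = 0;
    for (int k = 0; k < 4; ++k)
      if (k != a) q[m++] = vcut(p[a], v[a], p[k], v[k]);
    add_tri(q[0], q[1], q[2], ref, area, vol);
  } else {  // ni == 2: quad split into two triangles
    int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
    Vec3 mac = vcut(p[A], v[A], p[C], v[C]);
    Vec3 mad = vcut(p[A], v[A], p[D], v[D]);
    Vec3 mbc = vcut(p[B], v[B], p[C], v[C]);
    Vec3 mbd = vcut(p[B], v[B], p[D], v[D]);
    Vec3 ref = {(p[A].x + p[B].x) / 2, (p[A].y + p[B].y) / 2,
                (p[A].z + p[B].z) / 2};
    add_tri(mac, mad, mbd, ref, area, vol);
    add_tri(mac, mbd, mbc, ref, area, vol);
  }
}

// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector field, IntegerVector dim,
                                   NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  static const int CUBE[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  // 6-tetra decomposition along diagonal v0-v6
  static const int TETS[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
  };
  double area = 0.0, vol = 0.0;
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double val[8]; int any = 0, all = 1;
        Vec3 pos[8];
        for (int c = 0; c < 8; ++c) {
          int cx = x + CUBE[c][0], cy = y + CUBE[c][1], cz = z + CUBE[c][2];
          double v = 0.0;
          if (cx >= 0 && cy >= 0 && cz >= 0 && cx < nx && cy < ny && cz < nz)
            v = field[cx + nx * (cy + (R_xlen_t)ny * cz)];
          int in = v > 0.5;
          val[c] = v; any |= in; all &= in;
          pos[c].x = cx * sx; pos[c].y = cy * sy; pos[c].z = cz * sz;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          Vec3 p[4]; double v[4];
          for (int k = 0; k < 4; ++k) {
            p[k] = pos[TETS[t][k]];
            v[k] = val[TETS[t][k]];
          }
          do_tet(p, v, area, vol);
        }
      }
  return NumericVector::create(area, std::fabs(vol));
}
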