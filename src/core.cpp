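#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Column-major linear index for 0-based (x,y,z) in a (nx,ny,nz) lattice.
static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// The 13 unique distance-1 direction vectors of the 26-neighbourhood
// (one of each +/- pair).
static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vals, IntegerVector dim,
                          NumericMatrix coords, int order) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = coords.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = clampd(coords(i, 0), 0.0, nx - 1.0);
    double y = clampd(coords(i, 1), 0.0, ny - 1.0);
    double z = clampd(coords(i, 2), 0.0, nz - 1.0);
    if (order == 0) {
      int xi = (int)std::lround(x), yi = (int)std::lround(y),
          zi = (int)std::lround(z);
      out[i] = vals[idx3(xi, yi, zi, nx, ny)];
    } else {
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
          z0 = (int)std::floor(z);
      if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
      if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
      if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
      double fx = x - x0, fy = y - y0, fz = z - z0;
      double c000 = vals[idx3(x0, y0, z0, nx, ny)];
      double c100 = vals[idx3(x0 + 1, y0, z0, nx, ny)];
      double c010 = vals[idx3(x0, y0 + 1, z0, nx, ny)];
      double c110 = vals[idx3(x0 + 1, y0 + 1, z0, nx, ny)];
      double c001 = vals[idx3(x0, y0, z0 + 1, nx, ny)];
      double c101 = vals[idx3(x0 + 1, y0, z0 + 1, nx, ny)];
      double c011 = vals[idx3(x0, y0 + 1, z0 + 1, nx, ny)];
      double c111 = vals[idx3(x0 + 1, y0 + 1, z0 + 1, nx, ny)];
      double c00 = c000 * (1 - fx) + c100 * fx;
      double c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx;
      double c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[i] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma, renormalised
// at the borders (normalised convolution).
static void smooth_axis(std::vector<double>& buf, std::vector<double>& tmp,
                        int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  if (radius < 1) radius = 1;
  std::vector<double> k(2 * radius + 1);
  for (int i = -radius; i <= radius; ++i)
    k[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
  const int n[3] = {nx, ny, nz};
  const int len = n[axis];
  int stride = 1;
  for (int a = 0; a < axis; ++a) stride *= n[a];
  const int total = nx * ny * nz;
  const int nlines = total / len;
  std::vector<double> line(len);
  for (int l = 0; l < nlines; ++l) {
    // Decompose line index into a base offset skipping `axis`.
    int rem = l, base = 0, mult = 1;
    for (int a = 0; a < 3; ++a) {
      if (a == axis) { mult *= n[a]; continue; }
      int c = rem % n[a];
      rem /= n[a];
      base += c * mult;
      mult *= n[a];
    }
    for (int i = 0; i < len; ++i) line[i] = buf[base + i * stride];
    for (int i = 0; i < len; ++i) {
      double s = 0, w = 0;
      int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
      for (int j = lo; j <= hi; ++j) {
        double kv = k[j - i + radius];
        s += kv * line[j];
        w += kv;
      }
      tmp[base + i * stride] = s / w;
    }
  }
  buf.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth3(NumericVector vals, IntegerVector dim,
                                   NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(vals.begin(), vals.end()), tmp(buf.size());
  smooth_axis(buf, tmp, nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(buf, tmp, nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(buf, tmp, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(buf.begin(), buf.end());
  return out;
}

// Cubic box mean of radius r, renormalised at the borders.
// [[Rcpp::export]]
NumericVector cpp_box_mean3(NumericVector vals, IntegerVector dim, int r) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vals.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0;
        int cnt = 0;
        int x0 = std::max(0, x - r), x1 = std::min(nx - 1, x + r);
        int y0 = std::max(0, y - r), y1 = std::min(ny - 1, y + r);
        int z0 = std::max(0, z - r), z1 = std::min(nz - 1, z + r);
        for (int zz = z0; zz <= z1; ++zz)
          for (int yy = y0; yy <= y1; ++yy)
            for (int xx = x0; xx <= x1; ++xx) {
              s += vals[idx3(xx, yy, zz, nx, ny)];
              ++cnt;
            }
        out[idx3(x, y, z, nx, ny)] = s / cnt;
      }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gradient3(NumericVector vals, IntegerVector dim,
                            NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix g(nx * ny * nz, 3);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        int xm = x > 0 ? x - 1 : x, xp = x < nx - 1 ? x + 1 : x;
        int ym = y > 0 ? y - 1 : y, yp = y < ny - 1 ? y + 1 : y;
        int zm = z > 0 ? z - 1 : z, zp = z < nz - 1 ? z + 1 : z;
        g(i, 0) = (vals[idx3(xp, y, z, nx, ny)] - vals[idx3(xm, y, z, nx, ny)]) /
                  ((xp - xm) * spacing[0]);
        g(i, 1) = (vals[idx3(x, yp, z, nx, ny)] - vals[idx3(x, ym, z, nx, ny)]) /
                  ((yp - ym) * spacing[1]);
        g(i, 2) = (vals[idx3(x, y, zp, nx, ny)] - vals[idx3(x, y, zm, nx, ny)]) /
                  ((zp - zm) * spacing[2]);
      }
  return g;
}

// Symmetric co-occurrence counts at distance 1, summed over the 13 unique
// 3D directions. Both voxels must lie inside the mask.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, LogicalVector inmask,
                       IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix P(G, G);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!inmask[i]) continue;
        int li = levels[i];
        for (int d = 0; d < 13; ++d) {
          int xx = x + DIR13[d][0], yy = y + DIR13[d][1], zz = z + DIR13[d][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (!inmask[j]) continue;
          int lj = levels[j];
          P(li - 1, lj - 1) += 1.0;
          P(lj - 1, li - 1) += 1.0;
        }
      }
  return P;
}

// Run-length counts over the 13 unique directions.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, LogicalVector inmask,
                        IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxrun = std::max(nx, std::max(ny, nz));
  // Diagonal runs cannot exceed the smallest traversal, but max dim bounds all.
  NumericMatrix R(G, maxrun);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (!inmask[i]) continue;
          int px = x - dx, py = y - dy, pz = z - dz;
          bool start = true;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz) {
            int pi = idx3(px, py, pz, nx, ny);
            if (inmask[pi] && levels[pi] == levels[i]) start = false;
          }
          if (!start) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
            int ci = idx3(cx, cy, cz, nx, ny);
            if (!inmask[ci] || levels[ci] != levels[i]) break;
            ++len;
            cx += dx; cy += dy; cz += dz;
          }
          R(levels[i] - 1, len - 1) += 1.0;
        }
  }
  return R;
}

// 26-connected equal-level zones; returns a two-column matrix (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, LogicalVector inmask,
                              IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int total = nx * ny * nz;
  std::vector<char> seen(total, 0);
  std::vector<int> zl, zs, stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!inmask[i] || seen[i]) continue;
        int lev = levels[i], size = 0;
        stack.clear();
        stack.push_back(i);
        seen[i] = 1;
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          ++size;
          int cz = cur / (nx * ny), rem = cur % (nx * ny);
          int cy = rem / nx, cx = rem % nx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz)
                  continue;
                int j = idx3(xx, yy, zz, nx, ny);
                if (!seen[j] && inmask[j] && levels[j] == lev) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
        }
        zl.push_back(lev);
        zs.push_back(size);
      }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) {
    out(k, 0) = zl[k];
    out(k, 1) = zs[k];
  }
  return out;
}

// Dependence counts: for each in-mask voxel, the number of 26-neighbours
// (in mask) whose level differs from the centre by at most alpha.
// Returns a G x 27 matrix, column j+1 for dependence j in 0..26.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, LogicalVector inmask,
                       IntegerVector dim, int G, double alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix P(G, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!inmask[i]) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                  zz < 0 || zz >= nz)
                continue;
              int j = idx3(xx, yy, zz, nx, ny);
              if (inmask[j] && std::abs(levels[j] - levels[i]) <= alpha) ++dep;
            }
        P(levels[i] - 1, dep) += 1.0;
      }
  return P;
}

// 26-connected component of a binary mask containing the (0-based) seed index.
// [[Rcpp::export]]
LogicalVector cpp_connected_component(LogicalVector mask, IntegerVector dim,
                                      int seed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int total = nx * ny * nz;
  LogicalVector out(total);
  if (seed < 0 || seed >= total || !mask[seed]) return out;
  std::vector<int> stack;
  stack.push_back(seed);
  out[seed] = true;
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int cz = cur / (nx * ny), rem = cur % (nx * ny);
    int cy = rem / nx, cx = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = cx + dx, yy = cy + dy, zz = cz + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (mask[j] && !out[j]) {
            out[j] = true;
            stack.push_back(j);
          }
        }
  }
  return out;
}

// ---- Marching tetrahedra surface mesh: total area and enclosed volume ----

struct V3 { double x, y, z; };
static inline V3 vsub(const V3& a, const V3& b) {
  V3 r = {a.x - b.x, a.y - b.y, a.z - b.z}; return r;
}
static inline V3 vcross(const V3& a, const V3& b) {
  V3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
  return r;
}
static inline double vdot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

static inline V3 edge_point(const V3& p0, const V3& p1, double v0, double v1,
                            double iso) {
  double t = (iso - v0) / (v1 - v0);
  V3 r = {p0.x + t * (p1.x - p0.x), p0.y + t * (p1.y - p0.y),
          p0.z + t * (p1.z - p0.z)};
  return r;
}

// Accumulate one oriented triangle: normal forced to point away from `ref`
// (a point inside the iso-region), area and signed volume updated.
static void add_tri(V3 a, V3 b, V3 c, const V3& ref, double& area,
                    double& vol) {
  V3 n = vcross(vsub(b, a), vsub(c, a));
  V3 cen = {(a.x + b.x + c.x) / 3 - ref.x, (a.y + b.y + c.y) / 3 - ref.y,
            (a.z + b.z + c.z) / 3 - ref.z};
  if (vdot(n, cen) < 0) { V3 t = b; b = c; c = t; n = vcross(vsub(b, a), vsub(c, a)); }
  double nn = std::sqrt(vdot(n, n));
  area += 0.5 * nn;
  // Divergence theorem with outward orientation.
  vol += (a.x * (b.y * c.z - b.z * c.y) - a.y * (b.x * c.z - b.z * c.x) +
          a.z * (b.x * c.y - b.y * c.x)) / 6.0;
}

static void march_tet(const V3 p[4], const double v[4], double iso,
                      double& area, double& vol) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = v[i] >= iso; nin += in[i]; }
  if (nin == 0 || nin == 4) return;
  int ins[4], outs[4], ni = 0, no = 0;
  for (int i = 0; i < 4; ++i) (in[i] ? ins[ni++] : outs[no++]) = i;
  if (nin == 1 || nin == 3) {
    int a = (nin == 1) ? ins[0] : outs[0];
    int o[3];
    int k = 0;
    for (int i = 0; i < 4; ++i) if (i != a) o[k++] = i;
    V3 e0 = edge_point(p[a], p[o[0]], v[a], v[o[0]], iso);
    V3 e1 = edge_point(p[a], p[o[1]], v[a], v[o[1]], iso);
    V3 e2 = edge_point(p[a], p[o[2]], v[a], v[o[2]], iso);
    V3 ref = (nin == 1) ? p[a] : p[o[0]]; // an inside vertex
    if (nin == 3) ref = p[ins[0]];
    add_tri(e0, e1, e2, ref, area, vol);
  } else { // 2 in, 2 out -> quad
    int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
    V3 eac = edge_point(p[a], p[c], v[a], v[c], iso);
    V3 ead = edge_point(p[a], p[d], v[a], v[d], iso);
    V3 ebc = edge_point(p[b], p[c], v[b], v[c], iso);
    V3 ebd = edge_point(p[b], p[d], v[b], v[d], iso);
    V3 ref = {(p[a].x + p[b].x) / 2, (p[a].y + p[b].y) / 2,
              (p[a].z + p[b].z) / 2};
    add_tri(eac, ead, ebd, ref, area, vol);
    add_tri(eac, ebd, ebc, ref, area, vol);
  }
}

// Standard 6-tetrahedron decomposition of each cell around diagonal 0-6.
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};

// [[Rcpp::export]]
NumericVector cpp_mesh_volume_area(NumericVector vals, IntegerVector dim,
                                   NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double area = 0, vol = 0;
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double cv[8];
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          cv[c] = vals[idx3(x + CORNER[c][0], y + CORNER[c][1],
                            z + CORNER[c][2], nx, ny)];
          (cv[c] >= iso ? anyin : anyout) = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          V3 p[4];
          double v[4];
          for (int k = 0; k < 4; ++k) {
            int c = TETS[t][k];
            p[k].x = (x + CORNER[c][0]) * spacing[0];
            p[k].y = (y + CORNER[c][1]) * spacing[1];
            p[k].z = (z + CORNER[c][2]) * spacing[2];
            v[k] = cv[c];
          }
          march_tet(p, v, iso, area, vol);
        }
      }
  return NumericVector::create(std::fabs(vol), area);
}

// Maximum 3D diameter and the three maximum in-plane 2D diameters over
// boundary voxels (mm). Order: 3D, slice (xy), column (xz), row (yz).
// [[Rcpp::export]]
NumericVector cpp_max_diameters(LogicalVector mask, IntegerVector dim,
                                NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> bx, by, bz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        bool boundary = false;
        const int N6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int d = 0; d < 6 && !boundary; ++d) {
          int xx = x + N6[d][0], yy = y + N6[d][1], zz = z + N6[d][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz ||
              !mask[idx3(xx, yy, zz, nx, ny)])
            boundary = true;
        }
        if (boundary) { bx.push_back(x); by.push_back(y); bz.push_back(z); }
      }
  const size_t nb = bx.size();
  double d3 = 0, dxy = 0, dxz = 0, dyz = 0;
  for (size_t i = 0; i < nb; ++i)
    for (size_t j = i + 1; j < nb; ++j) {
      double ddx = (bx[i] - bx[j]) * spacing[0];
      double ddy = (by[i] - by[j]) * spacing[1];
      double ddz = (bz[i] - bz[j]) * spacing[2];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > d3) d3 = d2;
      if (bz[i] == bz[j] && ddx * ddx + ddy * ddy > dxy)
        dxy = ddx * ddx + ddy * ddy;
      if (by[i] == by[j] && ddx * ddx + ddz * ddz > dxz)
        dxz = ddx * ddx + ddz * ddz;
      if (bx[i] == bx[j] && ddy * ddy + ddz * ddz > dyz)
        dyz = ddy * ddy + ddz * ddz;
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dxy), std::sqrt(dxz),
                               std::sqrt(dyz));
}
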