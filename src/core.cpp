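// Voxel-level primitives for trabecular image analysis.
//
// All grids are 3-D logical/numeric R arrays with dim = (nz, ny, nx),
// column-major as stored by R, i.e. linear index = z + nz*(y + ny*x).
// Directions and coordinates at the C++ interface are (x, y, z) in voxel
// units; callers convert to physical units.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// ---------------------------------------------------------------------------
// MIL sampling: parallel test-line grids per direction.
//
// For each unit direction w a square grid of parallel lines perpendicular to
// w (spacing `spacing` voxels, origin dithered by `jitter`, one pair per
// direction) is marched through the volume at `step`-voxel increments with
// nearest-neighbour lookup.  Phase boundary crossings (value changes between
// consecutive in-volume samples) and in-volume path length are accumulated.
// [[Rcpp::export]]
NumericMatrix cpp_mil_sample(LogicalVector grid, IntegerVector dims,
                             NumericMatrix dirs, double spacing, double step,
                             NumericMatrix jitter) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int nd = dirs.nrow();
  NumericMatrix out(nd, 2); // total length, crossings
  const double cx = nx / 2.0, cy = ny / 2.0, cz = nz / 2.0;
  const double R = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny + (double)nz * nz) + 1.0;
  const int * g = LOGICAL(grid);

  for (int d = 0; d < nd; ++d) {
    double wx = dirs(d, 0), wy = dirs(d, 1), wz = dirs(d, 2);
    // orthonormal basis (u, v) spanning the plane normal to w
    double ax = 0, ay = 0, az = 0;
    if (std::fabs(wx) <= std::fabs(wy) && std::fabs(wx) <= std::fabs(wz)) ax = 1;
    else if (std::fabs(wy) <= std::fabs(wz)) ay = 1;
    else az = 1;
    double ux = wy * az - wz * ay, uy = wz * ax - wx * az, uz = wx * ay - wy * ax;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    double vx = wy * uz - wz * uy, vy = wz * ux - wx * uz, vz = wx * uy - wy * ux;

    double ja = jitter(d, 0) * spacing, jb = jitter(d, 1) * spacing;
    long crossings = 0, inside = 0;
    const double sx = wx * step, sy = wy * step, sz = wz * step;

    for (double a = -R + ja; a <= R; a += spacing) {
      for (double b = -R + jb; b <= R; b += spacing) {
        double ox = cx + a * ux + b * vx;
        double oy = cy + a * uy + b * vy;
        double oz = cz + a * uz + b * vz;
        // clip the ray o + t*w to the volume box (slab method)
        double tmin = -R, tmax = R;
        bool miss = false;
        const double o3[3] = {ox, oy, oz}, w3[3] = {wx, wy, wz};
        const double hi3[3] = {(double)nx, (double)ny, (double)nz};
        for (int ax2 = 0; ax2 < 3 && !miss; ++ax2) {
          if (std::fabs(w3[ax2]) < 1e-12) {
            if (o3[ax2] < 0 || o3[ax2] >= hi3[ax2]) miss = true;
          } else {
            double t0 = (0.0 - o3[ax2]) / w3[ax2];
            double t1 = (hi3[ax2] - o3[ax2]) / w3[ax2];
            if (t0 > t1) std::swap(t0, t1);
            if (t0 > tmin) tmin = t0;
            if (t1 < tmax) tmax = t1;
          }
        }
        if (miss || tmax <= tmin) continue;
        int s0 = (int)std::ceil(tmin / step), s1 = (int)std::floor(tmax / step);
        // phase-change counting with run persistence: a crossing is counted
        // only when the new phase holds for two consecutive samples, which
        // suppresses single-sample blips from voxelized interface staircases
        // (these would otherwise make MIL systematically direction-dependent)
        int conf = -1, cand = -1; // confirmed phase, candidate phase
        double px = ox + s0 * sx, py = oy + s0 * sy, pz = oz + s0 * sz;
        for (int s = s0; s <= s1; ++s, px += sx, py += sy, pz += sz) {
          int ix = (int)std::floor(px), iy = (int)std::floor(py), iz = (int)std::floor(pz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
            conf = -1; cand = -1;
            continue;
          }
          int val = g[vidx(iz, iy, ix, nz, ny)] ? 1 : 0;
          ++inside;
          if (conf < 0) {
            if (cand == val) conf = val; else cand = val;
          } else if (val != conf) {
            if (cand == val) { ++crossings; conf = val; cand = -1; }
            else cand = val;
          } else {
            cand = -1;
          }
        }
      }
    }
    out(d, 0) = inside * step;
    out(d, 1) = (double)crossings;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance from each voxel of the selected phase to the nearest voxel of the
// opposite phase, in voxel units.  Opposite-phase voxels get 0.
static void dt1d(const std::vector<double> &f, std::vector<double> &dout, int n,
                 std::vector<int> &v, std::vector<double> &zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    dout[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector grid, IntegerVector dims, bool foreground) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  const double INF = 1e18;
  const int * g = LOGICAL(grid);
  for (R_xlen_t i = 0; i < n; ++i) {
    bool in_phase = foreground ? (g[i] != 0) : (g[i] == 0);
    out[i] = in_phase ? INF : 0.0;
  }
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), dcol(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = out[vidx(z, y, x, nz, ny)];
      dt1d(f, dcol, nz, v, zbuf);
      for (int z = 0; z < nz; ++z) out[vidx(z, y, x, nz, ny)] = dcol[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = out[vidx(z, y, x, nz, ny)];
      dt1d(f, dcol, ny, v, zbuf);
      for (int y = 0; y < ny; ++y) out[vidx(z, y, x, nz, ny)] = dcol[y];
    }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[vidx(z, y, x, nz, ny)];
      dt1d(f, dcol, nx, v, zbuf);
      for (int x = 0; x < nx; ++x) out[vidx(z, y, x, nz, ny)] = dcol[x];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness (Hildebrand-Rueegsegger): thickness at a voxel is the
// diameter of the largest sphere fully inside the phase that contains it.
// Distance ridge voxels (spheres not contained in a neighbour's sphere) are
// painted back over the phase.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector grid, IntegerVector dims, bool foreground) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector ed2 = cpp_edt_sq(grid, dims, foreground);
  NumericVector th2(n); // squared radius of covering sphere
  const int * g = LOGICAL(grid);

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = vidx(z, y, x, nz, ny);
        bool in_phase = foreground ? (g[i] != 0) : (g[i] == 0);
        if (!in_phase || ed2[i] <= 0) continue;
        if (ed2[i] > 1e12)
          stop("no opposite-phase voxel present: thickness is unbounded");
        double r = std::sqrt(ed2[i]);
        // redundant if a neighbour's sphere contains this one
        bool redundant = false;
        for (int dx = -1; dx <= 1 && !redundant; ++dx)
          for (int dy = -1; dy <= 1 && !redundant; ++dy)
            for (int dz = -1; dz <= 1 && !redundant; ++dz) {
              if (!dx && !dy && !dz) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
              R_xlen_t j = vidx(Z, Y, X, nz, ny);
              if (ed2[j] <= ed2[i]) continue;
              double dd = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (std::sqrt(ed2[j]) >= r + dd - 1e-9) redundant = true;
            }
        if (redundant) continue;
        // paint the sphere
        int ir = (int)std::floor(r);
        for (int dx = -ir; dx <= ir; ++dx)
          for (int dy = -ir; dy <= ir; ++dy)
            for (int dz = -ir; dz <= ir; ++dz) {
              double dd2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
              if (dd2 > ed2[i]) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
              R_xlen_t j = vidx(Z, Y, X, nz, ny);
              bool jp = foreground ? (g[j] != 0) : (g[j] == 0);
              if (jp && ed2[i] > th2[j]) th2[j] = ed2[i];
            }
      }
  // diameter in voxels; phase voxels never reached by a painted sphere
  // (thin single-voxel structures) get their own EDT diameter
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    bool in_phase = foreground ? (g[i] != 0) : (g[i] == 0);
    if (!in_phase) { out[i] = 0.0; continue; }
    double r2 = th2[i] > 0 ? th2[i] : ed2[i];
    out[i] = 2.0 * std::sqrt(r2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of the foreground, 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector grid, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  const int * g = LOGICAL(grid);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!g[start] || lab[start]) continue;
    ++next;
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
            R_xlen_t j = vidx(Z, Y, X, nz, ny);
            if (g[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra (6-tetrahedra cell decomposition
// around the main cell diagonal, linear interpolation on edges).  Returns
// total triangle area in voxel^2; the mesh lives on the (n-1)^3 cell grid,
// so faces clipped by the volume boundary are naturally excluded.
static inline void interp(const double *p0, const double *p1, double f0, double f1,
                          double iso, double *out) {
  double t = (iso - f0) / (f1 - f0);
  out[0] = p0[0] + t * (p1[0] - p0[0]);
  out[1] = p0[1] + t * (p1[1] - p0[1]);
  out[2] = p0[2] + t * (p1[2] - p0[2]);
}

static inline double triarea(const double *a, const double *b, const double *c) {
  double u0 = b[0] - a[0], u1 = b[1] - a[1], u2 = b[2] - a[2];
  double v0 = c[0] - a[0], v1 = c[1] - a[1], v2 = c[2] - a[2];
  double cx = u1 * v2 - u2 * v1, cy = u2 * v0 - u0 * v2, cz = u0 * v1 - u1 * v0;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_mt_area(NumericVector field, IntegerVector dims, double iso) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  // cube corner offsets, bit 0 = x, bit 1 = y, bit 2 = z
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // 6 tetrahedra sharing diagonal 0-7
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double area = 0.0;
  const double * F = REAL(field);
  double cp[8][3], cf[8];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int X = x + corner[c][0], Y = y + corner[c][1], Z = z + corner[c][2];
          cf[c] = F[vidx(Z, Y, X, nz, ny)];
          cp[c][0] = X; cp[c][1] = Y; cp[c][2] = Z;
          if (cf[c] > iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int in[4], nin = 0, nout = 0, outv[4];
          for (int q = 0; q < 4; ++q) {
            if (cf[T[q]] > iso) in[nin++] = T[q]; else outv[nout++] = T[q];
          }
          if (nin == 0 || nin == 4) continue;
          double p1[3], p2[3], p3[3], p4[3];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : outv[0];
            const int *others = (nin == 1) ? outv : in;
            interp(cp[apex], cp[others[0]], cf[apex], cf[others[0]], iso, p1);
            interp(cp[apex], cp[others[1]], cf[apex], cf[others[1]], iso, p2);
            interp(cp[apex], cp[others[2]], cf[apex], cf[others[2]], iso, p3);
            area += triarea(p1, p2, p3);
          } else { // 2 in, 2 out -> quad
            interp(cp[in[0]], cp[outv[0]], cf[in[0]], cf[outv[0]], iso, p1);
            interp(cp[in[0]], cp[outv[1]], cf[in[0]], cf[outv[1]], iso, p2);
            interp(cp[in[1]], cp[outv[1]], cf[in[1]], cf[outv[1]], iso, p3);
            interp(cp[in[1]], cp[outv[0]], cf[in[1]], cf[outv[0]], iso, p4);
            area += triarea(p1, p2, p3) + triarea(p1, p3, p4);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Separable 1-D convolution along one axis (0 = z, 1 = y, 2 = x) with
// clamp-to-edge padding; kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_sep_convolve(NumericVector arr, IntegerVector dims,
                               NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int kl = kernel.size(), kh = kl / 2;
  NumericVector out((R_xlen_t)nz * ny * nx);
  const double * A = REAL(arr);
  const double * K = REAL(kernel);
  int nax = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0;
        for (int k = 0; k < kl; ++k) {
          int off = k - kh;
          int Z = z, Y = y, X = x;
          if (axis == 0) Z += off; else if (axis == 1) Y += off; else X += off;
          int c = (axis == 0) ? Z : (axis == 1) ? Y : X;
          if (c < 0) c = 0;
          if (c >= nax) c = nax - 1;
          if (axis == 0) Z = c; else if (axis == 1) Y = c; else X = c;
          s += K[k] * A[vidx(Z, Y, X, nz, ny)];
        }
        out[vidx(z, y, x, nz, ny)] = s;
      }
  return out;
}
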