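// Low-level voxel routines shared by the morphometry and phantom modules:
// exact anisotropic Euclidean distance transform, topology-preserving 3D
// thinning, connected-component labeling, separable Gaussian smoothing and
// isosurface area by marching tetrahedra.
//
// Arrays are passed as flat vectors in R's column-major order with
// dims = (n1, n2, n3) = (nz, ny, nx); index = z + nz*(y + ny*x).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + (long long)ny * x);
}

// ---------------------------------------------------------------------------
// Euclidean distance transform (Felzenszwalb & Huttenlocher lower envelope),
// run separably along each axis on squared distances with per-axis spacing.
// f holds squared distances; background voxels start at 0, foreground at Inf.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, double w) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (zb[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = fg[i] ? INF : 0.0;

  // pass along z (stride 1)
  {
    std::vector<double> f(nz), d(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int z = 0; z < nz; ++z) f[z] = D[base + z];
        dt1d(f, d, spacing[0]);
        for (int z = 0; z < nz; ++z) D[base + z] = d[z];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) f[y] = D[idx3(z, y, x, nz, ny)];
        dt1d(f, d, spacing[1]);
        for (int y = 0; y < ny; ++y) D[idx3(z, y, x, nz, ny)] = d[y];
      }
  }
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < nx; ++x) f[x] = D[idx3(z, y, x, nz, ny)];
        dt1d(f, d, spacing[2]);
        for (int x = 0; x < nx; ++x) D[idx3(z, y, x, nz, ny)] = d[x];
      }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(D[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (6/18/26 connectivity), BFS in scan order.
// Labels are assigned 1..K in order of first-encountered voxel.
// ---------------------------------------------------------------------------

static void neighbor_offsets(int connectivity, std::vector<std::array<int,3> >& offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dz, dy, dx});
      }
}

// [[Rcpp::export(name = ".cpp_label")]]
IntegerVector cpp_label(LogicalVector fg, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3> > offs;
  neighbor_offsets(connectivity, offs);
  int next = 0;
  std::queue<std::array<int,3> > q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!fg[i] || lab[i]) continue;
        lab[i] = ++next;
        q.push({z, y, x});
        while (!q.empty()) {
          std::array<int,3> c = q.front(); q.pop();
          for (size_t k = 0; k < offs.size(); ++k) {
            int zz = c[0] + offs[k][0], yy = c[1] + offs[k][1], xx = c[2] + offs[k][2];
            if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx) continue;
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (fg[j] && !lab[j]) { lab[j] = next; q.push({zz, yy, xx}); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point test for 3D thinning (26-connected foreground, 6-connected
// background). A voxel is simple iff exactly one 26-component of foreground
// in its 3x3x3 punctured neighborhood and exactly one 6-component of
// background within the 18-neighborhood touching a face neighbor.
// ---------------------------------------------------------------------------

static const int DZ[26] = {-1,-1,-1,-1,-1,-1,-1,-1,-1, 0,0,0,0,0,0,0,0, 1,1,1,1,1,1,1,1,1};
static const int DY[26] = {-1,-1,-1, 0,0,0, 1,1,1, -1,-1,-1,0,0,1,1,1, -1,-1,-1,0,0,0,1,1,1};
static const int DX[26] = {-1, 0, 1,-1,0,1,-1,0,1, -1, 0, 1,-1,1,-1,0,1, -1,0,1,-1,0,1,-1,0,1};

static bool is_simple(const std::vector<unsigned char>& F, int z, int y, int x,
                      int nz, int ny, int nx) {
  // gather 3x3x3 neighborhood as bool, index 0..26 with center at (1,1,1)
  bool nb[3][3][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        bool v = false;
        if (zz >= 0 && yy >= 0 && xx >= 0 && zz < nz && yy < ny && xx < nx)
          v = F[idx3(zz, yy, xx, nz, ny)] != 0;
        nb[dz + 1][dy + 1][dx + 1] = v;
      }

  // T26: number of 26-components of foreground in punctured neighborhood
  int compFG = 0;
  bool seen[3][3][3] = {{{false}}};
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) for (int c = 0; c < 3; ++c) {
    if (a == 1 && b == 1 && c == 1) continue;
    if (!nb[a][b][c] || seen[a][b][c]) continue;
    ++compFG;
    if (compFG > 1) return false;
    std::queue<std::array<int,3> > q;
    q.push({a, b, c});
    seen[a][b][c] = true;
    while (!q.empty()) {
      std::array<int,3> u = q.front(); q.pop();
      for (int da = -1; da <= 1; ++da) for (int db = -1; db <= 1; ++db) for (int dc = -1; dc <= 1; ++dc) {
        int aa = u[0] + da, bb = u[1] + db, cc = u[2] + dc;
        if (aa < 0 || bb < 0 || cc < 0 || aa > 2 || bb > 2 || cc > 2) continue;
        if (aa == 1 && bb == 1 && cc == 1) continue;
        if (nb[aa][bb][cc] && !seen[aa][bb][cc]) { seen[aa][bb][cc] = true; q.push({aa, bb, cc}); }
      }
    }
  }
  if (compFG != 1) return false;

  // T6: 6-components of background restricted to the 18-neighborhood,
  // seeded from background face neighbors, 6-connectivity within N18.
  bool bseen[3][3][3] = {{{false}}};
  int compBG = 0;
  const int faces[6][3] = {{0,1,1},{2,1,1},{1,0,1},{1,2,1},{1,1,0},{1,1,2}};
  for (int fi = 0; fi < 6; ++fi) {
    int a = faces[fi][0], b = faces[fi][1], c = faces[fi][2];
    if (nb[a][b][c] || bseen[a][b][c]) continue;
    ++compBG;
    if (compBG > 1) return false;
    std::queue<std::array<int,3> > q;
    q.push({a, b, c});
    bseen[a][b][c] = true;
    while (!q.empty()) {
      std::array<int,3> u = q.front(); q.pop();
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int aa = u[0] + d6[k][0], bb = u[1] + d6[k][1], cc = u[2] + d6[k][2];
        if (aa < 0 || bb < 0 || cc < 0 || aa > 2 || bb > 2 || cc > 2) continue;
        if (aa == 1 && bb == 1 && cc == 1) continue;
        // restrict to N18: exclude the 8 corners
        if (std::abs(aa - 1) + std::abs(bb - 1) + std::abs(cc - 1) == 3) continue;
        if (!nb[aa][bb][cc] && !bseen[aa][bb][cc]) { bseen[aa][bb][cc] = true; q.push({aa, bb, cc}); }
      }
    }
  }
  return compBG == 1;
}

static int fg_neighbors26(const std::vector<unsigned char>& F, int z, int y, int x,
                          int nz, int ny, int nx) {
  int cnt = 0;
  for (int k = 0; k < 26; ++k) {
    int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
    if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx) continue;
    if (F[idx3(zz, yy, xx, nz, ny)]) ++cnt;
  }
  return cnt;
}

// [[Rcpp::export(name = ".cpp_thin")]]
LogicalVector cpp_thin(LogicalVector fg, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<unsigned char> F(n);
  for (R_xlen_t i = 0; i < n; ++i) F[i] = fg[i] ? 1 : 0;

  // Six directional sub-iterations: U, D, N, S, E, W. A candidate must
  // have its d-neighbor background AND its opposite neighbor foreground;
  // the second condition means a sheet one voxel thick along d cannot be
  // attacked from its flat side, only eroded from its rims. Without it a
  // two-voxel-wide ribbon (every voxel individually simple) is retracted
  // end to end in a single sequential pass and an elongated object can
  // collapse to a point.
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            R_xlen_t i = idx3(z, y, x, nz, ny);
            if (!F[i]) continue;
            int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
            bool border = (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx)
              ? true : (F[idx3(zz, yy, xx, nz, ny)] == 0);
            if (!border) continue;
            int zo = z - dirs[d][0], yo = y - dirs[d][1], xo = x - dirs[d][2];
            bool opp_fg = (zo < 0 || yo < 0 || xo < 0 || zo >= nz || yo >= ny || xo >= nx)
              ? false : (F[idx3(zo, yo, xo, nz, ny)] != 0);
            if (!opp_fg) continue;
            int nbr = fg_neighbors26(F, z, y, x, nz, ny, nx);
            if (nbr <= 1) continue;            // endpoint or isolated: keep
            if (is_simple(F, z, y, x, nz, ny, nx)) cand.push_back(i);
          }
      // sequential deletion with re-check preserves topology
      for (size_t k = 0; k < cand.size(); ++k) {
        R_xlen_t i = cand[k];
        int x = (int)(i / ((R_xlen_t)nz * ny));
        int rem = (int)(i % ((R_xlen_t)nz * ny));
        int y = rem / nz, z = rem % nz;
        if (fg_neighbors26(F, z, y, x, nz, ny, nx) <= 1) continue;
        if (!is_simple(F, z, y, x, nz, ny, nx)) continue;
        F[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = F[i] != 0;
  return out;
}

// [[Rcpp::export(name = ".cpp_neighbor_count")]]
IntegerVector cpp_neighbor_count(LogicalVector fg, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<unsigned char> F(n);
  for (R_xlen_t i = 0; i < n; ++i) F[i] = fg[i] ? 1 : 0;
  IntegerVector out(n, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (F[i]) out[i] = fg_neighbors26(F, z, y, x, nz, ny, nx);
      }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with reflected borders; sigma per axis in
// voxel units. sigma <= 0 leaves the axis untouched.
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& v, int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int k = -r; k <= r; ++k) { ker[k + r] = std::exp(-0.5 * k * k / (sigma * sigma)); s += ker[k + r]; }
  for (size_t k = 0; k < ker.size(); ++k) ker[k] /= s;
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(len), outl(len);
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 2 ? ny : nx;
  for (int a = 0; a < n1; ++a)
    for (int b = 0; b < n2; ++b) {
      for (int t = 0; t < len; ++t) {
        int z = axis == 0 ? t : (axis == 1 ? a : a);
        int y = axis == 1 ? t : (axis == 0 ? a : b);
        int x = axis == 2 ? t : b;
        line[t] = v[idx3(z, y, x, nz, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int k = -r; k <= r; ++k) {
          int u = t + k;
          if (u < 0) u = -u - 1;                 // reflect
          if (u >= len) u = 2 * len - u - 1;
          if (u < 0) u = 0; if (u >= len) u = len - 1;
          acc += ker[k + r] * line[u];
        }
        outl[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        int z = axis == 0 ? t : (axis == 1 ? a : a);
        int y = axis == 1 ? t : (axis == 0 ? a : b);
        int x = axis == 2 ? t : b;
        v[idx3(z, y, x, nz, ny)] = outl[t];
      }
    }
}

// [[Rcpp::export(name = ".cpp_gauss3d")]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims, NumericVector sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, nz, ny, nx, 0, sigma[0]);
  blur_axis(v, nz, ny, nx, 1, sigma[1]);
  blur_axis(v, nz, ny, nx, 2, sigma[2]);
  return NumericVector(v.begin(), v.end());
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra: each grid cell is split into six
// tetrahedra sharing the main diagonal; the iso-level crossing within each
// tetrahedron is triangulated by linear interpolation along its edges.
// Table-free and orientation-consistent across cells.
// ---------------------------------------------------------------------------

struct P3 { double z, y, x; };

static inline P3 lerp(const P3& a, const P3& b, double va, double vb, double iso) {
  double t = (iso - va) / (vb - va);
  P3 p; p.z = a.z + t * (b.z - a.z); p.y = a.y + t * (b.y - a.y); p.x = a.x + t * (b.x - a.x);
  return p;
}

static inline double tri_area(const P3& a, const P3& b, const P3& c) {
  double uz = b.z - a.z, uy = b.y - a.y, ux = b.x - a.x;
  double vz = c.z - a.z, vy = c.y - a.y, vx = c.x - a.x;
  double cz = uy * vx - ux * vy;
  double cy = ux * vz - uz * vx;
  double cx = uz * vy - uy * vz;
  return 0.5 * std::sqrt(cz * cz + cy * cy + cx * cx);
}

// [[Rcpp::export(name = ".cpp_mesh_area")]]
double cpp_mesh_area(NumericVector field, IntegerVector dims, NumericVector spacing, double iso) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  // cube corners in (dz,dy,dx); main diagonal corner 0 -> corner 6
  const int CD[8][3] = {
    {0,0,0},{0,0,1},{0,1,1},{0,1,0},{1,0,0},{1,0,1},{1,1,1},{1,1,0}
  };
  const int TETS[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}
  };
  double area = 0.0;
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        double cv[8];
        P3 cp[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int zz = z + CD[c][0], yy = y + CD[c][1], xx = x + CD[c][2];
          cv[c] = field[idx3(zz, yy, xx, nz, ny)];
          cp[c].z = zz * spacing[0]; cp[c].y = yy * spacing[1]; cp[c].x = xx * spacing[2];
          if (cv[c] >= iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int a = TETS[t][0], b = TETS[t][1], c = TETS[t][2], d = TETS[t][3];
          int ids[4] = {a, b, c, d};
          int above[4], nab = 0, below[4], nbe = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[ids[k]] >= iso) above[nab++] = ids[k]; else below[nbe++] = ids[k];
          }
          if (nab == 0 || nab == 4) continue;
          if (nab == 1 || nab == 3) {
            int apex = nab == 1 ? above[0] : below[0];
            int oth[3]; int m = 0;
            for (int k = 0; k < 4; ++k) if (ids[k] != apex) oth[m++] = ids[k];
            P3 p1 = lerp(cp[apex], cp[oth[0]], cv[apex], cv[oth[0]], iso);
            P3 p2 = lerp(cp[apex], cp[oth[1]], cv[apex], cv[oth[1]], iso);
            P3 p3 = lerp(cp[apex], cp[oth[2]], cv[apex], cv[oth[2]], iso);
            area += tri_area(p1, p2, p3);
          } else {
            // two above / two below: quad across the four mixed edges
            int a0 = above[0], a1 = above[1], b0 = below[0], b1 = below[1];
            P3 p1 = lerp(cp[a0], cp[b0], cv[a0], cv[b0], iso);
            P3 p2 = lerp(cp[a0], cp[b1], cv[a0], cv[b1], iso);
            P3 p3 = lerp(cp[a1], cp[b1], cv[a1], cv[b1], iso);
            P3 p4 = lerp(cp[a1], cp[b0], cv[a1], cv[b0], iso);
            area += tri_area(p1, p2, p3) + tri_area(p1, p3, p4);
          }
        }
      }
  return area;
}
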