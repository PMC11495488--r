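#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Array layout shared with the R side: values[y, x, z], column-major,
// so linear index = y + ny * (x + nx * z), all 0-based here.
static inline int vidx(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

// Rasterize an infinite cylinder (axis through p0 with unit direction d,
// radius r) clipped to the grid, OR-ing voxels into `vol` (modified in
// place). Returns the number of voxels newly set.
// [[Rcpp::export]]
int cpp_raster_cylinder(IntegerVector vol, IntegerVector dim,
                        NumericVector p0, NumericVector d, double radius) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const double dx = d[0], dy = d[1], dz = d[2];
  // param range of the axis segment inside the box padded by the radius
  double tmin = -1e18, tmax = 1e18;
  const double lo[3] = {-radius, -radius, -radius};
  const double hi[3] = {nx - 1 + radius, ny - 1 + radius, nz - 1 + radius};
  const double pp[3] = {p0[0], p0[1], p0[2]};
  const double dd[3] = {dx, dy, dz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dd[a]) < 1e-12) {
      if (pp[a] < lo[a] || pp[a] > hi[a]) return 0;
    } else {
      double t1 = (lo[a] - pp[a]) / dd[a], t2 = (hi[a] - pp[a]) / dd[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmin > tmax) return 0;
  int added = 0;
  const int rc = (int)std::ceil(radius) + 1;
  const double r2 = radius * radius;
  const double step = 0.5;
  for (double t = tmin; t <= tmax; t += step) {
    const double cx = pp[0] + t * dx, cy = pp[1] + t * dy, cz = pp[2] + t * dz;
    const int x0 = std::max(0, (int)std::floor(cx) - rc);
    const int x1 = std::min(nx - 1, (int)std::ceil(cx) + rc);
    const int y0 = std::max(0, (int)std::floor(cy) - rc);
    const int y1 = std::min(ny - 1, (int)std::ceil(cy) + rc);
    const int z0 = std::max(0, (int)std::floor(cz) - rc);
    const int z1 = std::min(nz - 1, (int)std::ceil(cz) + rc);
    for (int z = z0; z <= z1; ++z)
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y) {
          const int id = vidx(y, x, z, ny, nx);
          if (vol[id]) continue;
          // exact squared distance from voxel center to the axis line
          const double wx = x - pp[0], wy = y - pp[1], wz = z - pp[2];
          const double proj = wx * dx + wy * dy + wz * dz;
          const double d2 = wx * wx + wy * wy + wz * wz - proj * proj;
          if (d2 <= r2) { vol[id] = 1; ++added; }
        }
  }
  return added;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher lower envelope)
static void dt1d(const std::vector<double>& f, std::vector<double>& out,
                 int n, std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const double dq = q - v[k];
    out[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance transform of a binary mask: for each
// foreground voxel, squared distance to the nearest background voxel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const double INF = 1e18;
  NumericVector g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;
  const int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), out(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[vidx(y, x, z, ny, nx)];
      dt1d(f, out, ny, v, zb);
      for (int y = 0; y < ny; ++y) g[vidx(y, x, z, ny, nx)] = out[y];
    }
  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[vidx(y, x, z, ny, nx)];
      dt1d(f, out, nx, v, zb);
      for (int x = 0; x < nx; ++x) g[vidx(y, x, z, ny, nx)] = out[x];
    }
  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = g[vidx(y, x, z, ny, nx)];
      dt1d(f, out, nz, v, zb);
      for (int z = 0; z < nz; ++z) g[vidx(y, x, z, ny, nx)] = out[z];
    }
  return g;
}

// Model-independent local thickness (largest inscribed sphere diameter, in
// voxels): EDT -> distance ridge (spheres not contained in a neighbour's
// sphere) -> sphere painting. Voxels missed by painting fall back to twice
// their own EDT radius.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(IntegerVector mask, IntegerVector dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  NumericVector ed = cpp_edt_sq(mask, dim);
  NumericVector thick(mask.size());
  // 26-neighbour offsets and their lengths
  std::vector<int> oy, ox, oz;
  std::vector<double> olen;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (!a && !b && !c) continue;
        oy.push_back(a); ox.push_back(b); oz.push_back(c);
        olen.push_back(std::sqrt((double)(a * a + b * b + c * c)));
      }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        const int id = vidx(y, x, z, ny, nx);
        if (!mask[id]) continue;
        const double r = std::sqrt(ed[id]);
        bool ridge = true;
        for (size_t k = 0; k < oy.size(); ++k) {
          const int yy = y + oy[k], xx = x + ox[k], zz = z + oz[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
            continue;
          const int nid = vidx(yy, xx, zz, ny, nx);
          if (!mask[nid]) continue;
          if (std::sqrt(ed[nid]) >= r + olen[k] - 1e-9) { ridge = false; break; }
        }
        if (!ridge) continue;
        // paint the inscribed sphere
        const int rc = (int)std::ceil(r);
        const double r2 = r * r, dia = 2.0 * r;
        const int x0 = std::max(0, x - rc), x1 = std::min(nx - 1, x + rc);
        const int y0 = std::max(0, y - rc), y1 = std::min(ny - 1, y + rc);
        const int z0 = std::max(0, z - rc), z1 = std::min(nz - 1, z + rc);
        for (int zz = z0; zz <= z1; ++zz)
          for (int xx = x0; xx <= x1; ++xx)
            for (int yy = y0; yy <= y1; ++yy) {
              const double dd = (double)(yy - y) * (yy - y) +
                (double)(xx - x) * (xx - x) + (double)(zz - z) * (zz - z);
              if (dd > r2) continue;
              const int wid = vidx(yy, xx, zz, ny, nx);
              if (mask[wid] && thick[wid] < dia) thick[wid] = dia;
            }
      }
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    if (mask[i] && thick[i] == 0.0) thick[i] = 2.0 * std::sqrt(ed[i]);
  return thick;
}

// Trace parallel line grids through a spherical ROI for a set of directions.
// For each direction: total in-sphere line length (voxel units) and the
// number of background-to-foreground phase crossings along the sampled
// lines. dirs is n x 3 (x, y, z unit vectors); center is (x, y, z).
// [[Rcpp::export]]
NumericMatrix cpp_mil_trace(IntegerVector mask, IntegerVector dim,
                            NumericVector center, double radius,
                            NumericMatrix dirs, double spacing, double step) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const int nd = dirs.nrow();
  NumericMatrix out(nd, 2);
  for (int k = 0; k < nd; ++k) {
    double wx = dirs(k, 0), wy = dirs(k, 1), wz = dirs(k, 2);
    // orthonormal basis perpendicular to the direction
    double ax = 1, ay = 0, az = 0;
    if (std::fabs(wx) > 0.9) { ax = 0; ay = 1; }
    double ux = wy * az - wz * ay, uy = wz * ax - wx * az, uz = wx * ay - wy * ax;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    const double vx = wy * uz - wz * uy, vy = wz * ux - wx * uz,
      vz = wx * uy - wy * ux;
    double len = 0.0;
    double crossings = 0.0;
    for (double a = -radius; a <= radius; a += spacing)
      for (double b = -radius; b <= radius; b += spacing) {
        const double rho2 = a * a + b * b;
        if (rho2 >= radius * radius) continue;
        const double h = std::sqrt(radius * radius - rho2);
        const double ox = center[0] + a * ux + b * vx;
        const double oy = center[1] + a * uy + b * vy;
        const double oz = center[2] + a * uz + b * vz;
        int prev = -1;
        for (double s = -h; s <= h; s += step) {
          const int x = (int)std::lround(ox + s * wx);
          const int y = (int)std::lround(oy + s * wy);
          const int z = (int)std::lround(oz + s * wz);
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) {
            prev = -1;
            continue;
          }
          const int cur = mask[vidx(y, x, z, ny, nx)] ? 1 : 0;
          if (prev == 0 && cur == 1) crossings += 1.0;
          prev = cur;
        }
        len += 2.0 * h;
      }
    out(k, 0) = len;
    out(k, 1) = crossings;
  }
  return out;
}

// Connected-component labelling of a binary mask (connectivity 6 or 26).
// Returns integer labels, 0 for background, components numbered from 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  std::vector<int> oy, ox, oz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (!a && !b && !c) continue;
        if (connectivity == 6 && (std::abs(a) + std::abs(b) + std::abs(c)) != 1)
          continue;
        oy.push_back(a); ox.push_back(b); oz.push_back(c);
      }
  IntegerVector lab(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        const int id = vidx(y, x, z, ny, nx);
        if (!mask[id] || lab[id]) continue;
        ++next;
        lab[id] = next;
        stack.clear();
        stack.push_back(id);
        while (!stack.empty()) {
          const int cur = stack.back();
          stack.pop_back();
          const int cy = cur % ny;
          const int cx = (cur / ny) % nx;
          const int cz = cur / (ny * nx);
          for (size_t k = 0; k < oy.size(); ++k) {
            const int yy = cy + oy[k], xx = cx + ox[k], zz = cz + oz[k];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            const int nid = vidx(yy, xx, zz, ny, nx);
            if (mask[nid] && !lab[nid]) {
              lab[nid] = next;
              stack.push_back(nid);
            }
          }
        }
      }
  return lab;
}
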