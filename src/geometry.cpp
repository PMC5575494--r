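#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxelize a closed triangle mesh on a regular isotropic grid.
// A voxel is occupied iff its center lies inside the mesh, decided by
// casting a +z ray from the voxel center and counting triangle crossings
// (even-odd rule).  Crossings are accumulated per (x,y) column, so each
// triangle is visited once.  Column sample points carry a tiny constant
// jitter (well below any geometric tolerance) so rays through edges or
// vertices of the mesh are measure-zero.
//
// origin = center of voxel (0,0,0); spacing isotropic, mm.
// [[Rcpp::export]]
List cpp_voxelize(NumericMatrix verts, IntegerMatrix faces,
                  NumericVector origin, double spacing,
                  IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double jx = 0.37e-6 * spacing, jy = 0.61e-6 * spacing,
               jz = 0.53e-6 * spacing;

  std::vector< std::vector<double> > cross((size_t)nx * ny);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    const int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1, i2 = faces(f, 2) - 1;
    const double x0 = verts(i0, 0), y0 = verts(i0, 1), z0 = verts(i0, 2);
    const double x1 = verts(i1, 0), y1 = verts(i1, 1), z1 = verts(i1, 2);
    const double x2 = verts(i2, 0), y2 = verts(i2, 1), z2 = verts(i2, 2);
    const double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    // triangle parallel to z: projects to a degenerate segment, never hit
    const double scale = std::max({std::fabs(x1 - x0), std::fabs(x2 - x0),
                                   std::fabs(y1 - y0), std::fabs(y2 - y0), 1e-30});
    if (std::fabs(det) < 1e-14 * scale * scale) continue;

    const double xmin = std::min({x0, x1, x2}), xmax = std::max({x0, x1, x2});
    const double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    int ia = (int)std::ceil((xmin - ox - jx) / spacing);
    int ib = (int)std::floor((xmax - ox - jx) / spacing);
    int ja = (int)std::ceil((ymin - oy - jy) / spacing);
    int jb = (int)std::floor((ymax - oy - jy) / spacing);
    ia = std::max(ia, 0); ib = std::min(ib, nx - 1);
    ja = std::max(ja, 0); jb = std::min(jb, ny - 1);
    for (int j = ja; j <= jb; ++j) {
      const double py = oy + j * spacing + jy;
      for (int i = ia; i <= ib; ++i) {
        const double px = ox + i * spacing + jx;
        const double u = ((px - x0) * (y2 - y0) - (py - y0) * (x2 - x0)) / det;
        const double v = ((x1 - x0) * (py - y0) - (y1 - y0) * (px - x0)) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        const double zc = z0 + u * (z1 - z0) + v * (z2 - z0);
        cross[(size_t)j * nx + i].push_back(zc);
      }
    }
  }

  LogicalVector occ((R_xlen_t)nx * ny * nz, false);
  int odd_columns = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double> &c = cross[(size_t)j * nx + i];
      if (c.empty()) continue;
      std::sort(c.begin(), c.end());
      size_t m = c.size();
      if (m % 2 == 1) { ++odd_columns; --m; }
      for (size_t k = 0; k + 1 < m + 1; k += 2) {
        if (k + 1 >= m) break;
        const double zlo = c[k], zhi = c[k + 1];
        int ka = (int)std::ceil((zlo - oz - jz) / spacing);
        int kb = (int)std::floor((zhi - oz - jz) / spacing);
        ka = std::max(ka, 0); kb = std::min(kb, nz - 1);
        for (int kk = ka; kk <= kb; ++kk)
          occ[(R_xlen_t)kk * nx * ny + (R_xlen_t)j * nx + i] = true;
      }
    }
  }
  return List::create(_["occ"] = occ, _["odd_columns"] = odd_columns);
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const double *f, double *d, int n,
                 int *v, double *zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    if (f[q] == std::numeric_limits<double>::infinity()) continue;
    double s;
    while (true) {
      if (f[v[k]] == std::numeric_limits<double>::infinity()) {
        // drop unreachable parabola
        if (k == 0) { v[0] = q; zbuf[0] = -std::numeric_limits<double>::infinity(); zbuf[1] = std::numeric_limits<double>::infinity(); s = -std::numeric_limits<double>::infinity(); break; }
        --k;
        continue;
      }
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
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
    const double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared EDT of a binary grid: distance (in voxel units, squared) from each
// voxel center to the nearest occupied voxel center.  Returns +Inf if the
// mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d((R_xlen_t)nx * ny * nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;

  int nmax = std::max({nx, ny, nz});
  std::vector<double> f(nmax), dd(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // pass 1: along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)k * nxy + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) {
        f[i] = occ[base + i] ? 0.0 : INF;
        if (occ[base + i]) any = true;
      }
      if (!any) { for (int i = 0; i < nx; ++i) d[base + i] = INF; continue; }
      dt1d(f.data(), dd.data(), nx, v.data(), zbuf.data());
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }

  // pass 2: along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)k * nxy + i;
      bool fin = false;
      for (int j = 0; j < ny; ++j) {
        f[j] = d[base + (R_xlen_t)j * nx];
        if (f[j] < INF) fin = true;
      }
      if (!fin) continue;
      dt1d(f.data(), dd.data(), ny, v.data(), zbuf.data());
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)j * nx] = dd[j];
    }

  // pass 3: along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)j * nx + i;
      bool fin = false;
      for (int k = 0; k < nz; ++k) {
        f[k] = d[base + (R_xlen_t)k * nxy];
        if (f[k] < INF) fin = true;
      }
      if (!fin) continue;
      dt1d(f.data(), dd.data(), nz, v.data(), zbuf.data());
      for (int k = 0; k < nz; ++k) d[base + (R_xlen_t)k * nxy] = dd[k];
    }

  return d;
}

// ---- nearest-neighbor distances between point sets ----

// [[Rcpp::export]]
NumericVector cpp_nn_dist_brute(NumericMatrix q, NumericMatrix r) {
  const int nq = q.nrow(), nr = r.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double xi = q(i, 0), yi = q(i, 1), zi = q(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nr; ++j) {
      const double dx = xi - r(j, 0), dy = yi - r(j, 1), dz = zi - r(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Uniform-grid accelerated nearest neighbor.  Reference points are binned
// into cubic cells; each query expands Chebyshev shells of cells until the
// current best squared distance is certified.  The minimum squared distance
// found is the same number the brute scan finds, so results agree bit-exactly.
// [[Rcpp::export]]
NumericVector cpp_nn_dist_grid(NumericMatrix q, NumericMatrix r) {
  const int nq = q.nrow(), nr = r.nrow();
  NumericVector out(nq);
  if (nr == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = r(0, d); hi[d] = r(0, d); }
  for (int j = 1; j < nr; ++j)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], r(j, d));
      hi[d] = std::max(hi[d], r(j, d));
    }
  double span = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  // aim for ~2 points per cell
  double cell = span / std::max(1.0, std::cbrt((double)nr / 2.0));
  if (cell <= 0) cell = span;
  int ng[3];
  for (int d = 0; d < 3; ++d)
    ng[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);

  const size_t ncell = (size_t)ng[0] * ng[1] * ng[2];
  std::vector<int> head(ncell, -1), nxt(nr, -1);
  auto cell_of = [&](double x, double y, double z) -> size_t {
    int cx = std::min(ng[0] - 1, std::max(0, (int)((x - lo[0]) / cell)));
    int cy = std::min(ng[1] - 1, std::max(0, (int)((y - lo[1]) / cell)));
    int cz = std::min(ng[2] - 1, std::max(0, (int)((z - lo[2]) / cell)));
    return ((size_t)cz * ng[1] + cy) * ng[0] + cx;
  };
  for (int j = 0; j < nr; ++j) {
    size_t c = cell_of(r(j, 0), r(j, 1), r(j, 2));
    nxt[j] = head[c];
    head[c] = j;
  }

  for (int i = 0; i < nq; ++i) {
    const double xi = q(i, 0), yi = q(i, 1), zi = q(i, 2);
    int cx = (int)std::floor((xi - lo[0]) / cell);
    int cy = (int)std::floor((yi - lo[1]) / cell);
    int cz = (int)std::floor((zi - lo[2]) / cell);
    double best = std::numeric_limits<double>::infinity();
    const int kmax = std::max({ng[0], ng[1], ng[2],
                               std::abs(cx) + ng[0], std::abs(cy) + ng[1],
                               std::abs(cz) + ng[2]}) + 2;
    for (int k = 0; ; ++k) {
      if (k > 0 && best < std::numeric_limits<double>::infinity()) {
        // all cells at shell k are at least (k-1)*cell away from the query
        double safe = (double)(k - 1) * cell;
        if (safe * safe > best) break;
      }
      if (k > kmax) break;
      for (int dz = -k; dz <= k; ++dz) {
        int z = cz + dz;
        if (z < 0 || z >= ng[2]) continue;
        for (int dy = -k; dy <= k; ++dy) {
          int y = cy + dy;
          if (y < 0 || y >= ng[1]) continue;
          const bool face_z = (std::abs(dz) == k), face_y = (std::abs(dy) == k);
          for (int dx = -k; dx <= k; ++dx) {
            if (!face_z && !face_y && std::abs(dx) != k) continue; // shell only
            int x = cx + dx;
            if (x < 0 || x >= ng[0]) continue;
            size_t c = ((size_t)z * ng[1] + y) * ng[0] + x;
            for (int j = head[c]; j >= 0; j = nxt[j]) {
              const double ddx = xi - r(j, 0), ddy = yi - r(j, 1), ddz = zi - r(j, 2);
              const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best) best = d2;
            }
          }
        }
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- point to triangle-mesh surface distance (Ericson closest-point) ----

static double point_tri_d2(const double p[3], const double a[3],
                           const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d];
  }
  const double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  const double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int d=0;d<3;++d) q[d] = a[d]; goto done; }
  {
    double bp[3];
    for (int d = 0; d < 3; ++d) bp[d] = p[d] - b[d];
    const double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    const double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { for (int d=0;d<3;++d) q[d] = b[d]; goto done; }
    const double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      const double t = d1 / (d1 - d3);
      for (int d = 0; d < 3; ++d) q[d] = a[d] + t * ab[d];
      goto done;
    }
    double cp[3];
    for (int d = 0; d < 3; ++d) cp[d] = p[d] - c[d];
    const double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    const double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d6 >= 0.0 && d5 <= d6) { for (int d=0;d<3;++d) q[d] = c[d]; goto done; }
    const double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      const double t = d2 / (d2 - d6);
      for (int d = 0; d < 3; ++d) q[d] = a[d] + t * ac[d];
      goto done;
    }
    const double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      const double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int d = 0; d < 3; ++d) q[d] = b[d] + t * (c[d] - b[d]);
      goto done;
    }
    const double denom = 1.0 / (va + vb + vc);
    const double v = vb * denom, w = vc * denom;
    for (int d = 0; d < 3; ++d) q[d] = a[d] + ab[d] * v + ac[d] * w;
  }
done:
  const double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_surface_dist(NumericMatrix q, NumericMatrix verts,
                                     IntegerMatrix faces) {
  const int nq = q.nrow(), nf = faces.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double p[3] = { q(i, 0), q(i, 1), q(i, 2) };
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      const int i0 = faces(f,0)-1, i1 = faces(f,1)-1, i2 = faces(f,2)-1;
      const double a[3] = { verts(i0,0), verts(i0,1), verts(i0,2) };
      const double b[3] = { verts(i1,0), verts(i1,1), verts(i1,2) };
      const double c[3] = { verts(i2,0), verts(i2,1), verts(i2,2) };
      const double d2 = point_tri_d2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
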