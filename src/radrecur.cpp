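#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Shared 26-neighbourhood offset table; first 13 rows are the unique
// (non-antipodal) directions used for GLCM/GLRLM angles.
static const int OFF26[26][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1},
  {-1,0,0},{0,-1,0},{0,0,-1},
  {-1,-1,0},{-1,1,0},{-1,0,-1},{-1,0,1},{0,-1,-1},{0,-1,1},
  {-1,-1,-1},{-1,-1,1},{-1,1,-1},{-1,1,1}
};

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}
inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// ---- gray-level co-occurrence -------------------------------------------
// levels: 0 = not in ROI / excluded, 1..nlevels valid.
// Returns nlevels x nlevels x 13 symmetric counts (both orderings counted).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dim, int nlevels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(nlevels * nlevels * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = OFF26[d][0], dy = OFF26[d][1], dz = OFF26[d][2];
    double *M = &out[d * nlevels * nlevels];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          M[(a - 1) + nlevels * (b - 1)] += 1.0;
          M[(b - 1) + nlevels * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nlevels, nlevels, 13);
  return out;
}

// ---- gray-level run length ----------------------------------------------
// Returns nlevels x maxrun x 13 run counts.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int nlevels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector out(nlevels * maxrun * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = OFF26[d][0], dy = OFF26[d][1], dz = OFF26[d][2];
    double *M = &out[d * nlevels * maxrun];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inside(xp, yp, zp, nx, ny, nz) &&
              levels[idx3(xp, yp, zp, nx, ny)] == a)
            continue;  // not a run start
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (inside(xn, yn, zn, nx, ny, nz) &&
                 levels[idx3(xn, yn, zn, nx, ny)] == a) {
            ++len; xn += dx; yn += dy; zn += dz;
          }
          M[(a - 1) + nlevels * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nlevels, maxrun, 13);
  return out;
}

// ---- gray-level size zone -----------------------------------------------
// 26-connected zones of equal level; returns 2-column matrix (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (levels[i] == 0 || seen[i]) continue;
    int lev = levels[i], size = 0;
    seen[i] = 1; q.push(i);
    while (!q.empty()) {
      int j = q.front(); q.pop(); ++size;
      int x = j % nx, y = (j / nx) % ny, z = j / (nx * ny);
      for (int k = 0; k < 26; ++k) {
        int x2 = x + OFF26[k][0], y2 = y + OFF26[k][1], z2 = z + OFF26[k][2];
        if (!inside(x2, y2, z2, nx, ny, nz)) continue;
        int j2 = idx3(x2, y2, z2, nx, ny);
        if (!seen[j2] && levels[j2] == lev) { seen[j2] = 1; q.push(j2); }
      }
    }
    zl.push_back(lev); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  return out;
}

// ---- gray-level dependence ----------------------------------------------
// Dependence size j = 1 + number of 26-neighbours within |delta level| <= alpha.
// Returns nlevels x 27 counts.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int nlevels,
                       int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(nlevels, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int dep = 0;
        for (int k = 0; k < 26; ++k) {
          int x2 = x + OFF26[k][0], y2 = y + OFF26[k][1], z2 = z + OFF26[k][2];
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b != 0 && std::abs(b - a) <= alpha) ++dep;
        }
        out(a - 1, dep) += 1.0;
      }
  return out;
}

// ---- neighbouring gray tone difference ----------------------------------
// Returns nlevels x 2: column 0 = n_i (valid voxels of level i with at least
// one valid neighbour), column 1 = s_i (summed |level - neighbourhood mean|).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int nlevels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(nlevels, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int k = 0; k < 26; ++k) {
          int x2 = x + OFF26[k][0], y2 = y + OFF26[k][1], z2 = z + OFF26[k][2];
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b != 0) { sum += b; ++cnt; }
        }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs((double)a - sum / cnt);
      }
  return out;
}

// ---- connected-component labelling --------------------------------------
// connectivity 6 or 26; returns integer labels (0 outside mask).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2], n = nx * ny * nz;
  int nneigh = (connectivity == 6) ? 6 : 26;
  static const int OFF6[6][3] = {
    {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
  };
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    lab[i] = ++cur; q.push(i);
    while (!q.empty()) {
      int j = q.front(); q.pop();
      int x = j % nx, y = (j / nx) % ny, z = j / (nx * ny);
      for (int k = 0; k < nneigh; ++k) {
        int dx, dy, dz;
        if (connectivity == 6) { dx = OFF6[k][0]; dy = OFF6[k][1]; dz = OFF6[k][2]; }
        else { dx = OFF26[k][0]; dy = OFF26[k][1]; dz = OFF26[k][2]; }
        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
        if (!inside(x2, y2, z2, nx, ny, nz)) continue;
        int j2 = idx3(x2, y2, z2, nx, ny);
        if (mask[j2] != 0 && lab[j2] == 0) { lab[j2] = cur; q.push(j2); }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = cur;
  return lab;
}

// ---- resampling ----------------------------------------------------------
// Keys cubic convolution kernel, a = -0.5.
inline double keys(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}
inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sample input volume at continuous voxel coordinates of the output grid.
// in_spacing / out_spacing in mm; both grids share the origin at voxel (0,0,0).
// order = 3 (tricubic, clamped edges) or 1 (trilinear).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vals, IntegerVector dim,
                           NumericVector in_spacing, IntegerVector out_dim,
                           NumericVector out_spacing, int order) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((double)ox * oy * oz);
  for (int z = 0; z < oz; ++z) {
    double fz = z * out_spacing[2] / in_spacing[2];
    for (int y = 0; y < oy; ++y) {
      double fy = y * out_spacing[1] / in_spacing[1];
      for (int x = 0; x < ox; ++x) {
        double fx = x * out_spacing[0] / in_spacing[0];
        double v = 0.0;
        if (order == 1) {
          int x0 = clampi((int)std::floor(fx), 0, nx - 1);
          int y0 = clampi((int)std::floor(fy), 0, ny - 1);
          int z0 = clampi((int)std::floor(fz), 0, nz - 1);
          int x1 = clampi(x0 + 1, 0, nx - 1);
          int y1 = clampi(y0 + 1, 0, ny - 1);
          int z1 = clampi(z0 + 1, 0, nz - 1);
          double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          tx = tx < 0 ? 0 : (tx > 1 ? 1 : tx);
          ty = ty < 0 ? 0 : (ty > 1 ? 1 : ty);
          tz = tz < 0 ? 0 : (tz > 1 ? 1 : tz);
          for (int c = 0; c < 8; ++c) {
            int bx = c & 1, by = (c >> 1) & 1, bz = (c >> 2) & 1;
            double w = (bx ? tx : 1 - tx) * (by ? ty : 1 - ty) * (bz ? tz : 1 - tz);
            v += w * vals[idx3(bx ? x1 : x0, by ? y1 : y0, bz ? z1 : z0, nx, ny)];
          }
        } else {
          int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
              z0 = (int)std::floor(fz);
          for (int kz = -1; kz <= 2; ++kz) {
            double wz = keys(fz - (z0 + kz));
            if (wz == 0.0) continue;
            int zz = clampi(z0 + kz, 0, nz - 1);
            for (int ky = -1; ky <= 2; ++ky) {
              double wy = keys(fy - (y0 + ky));
              if (wy == 0.0) continue;
              int yy = clampi(y0 + ky, 0, ny - 1);
              for (int kx = -1; kx <= 2; ++kx) {
                double wx = keys(fx - (x0 + kx));
                if (wx == 0.0) continue;
                int xx = clampi(x0 + kx, 0, nx - 1);
                v += wx * wy * wz * vals[idx3(xx, yy, zz, nx, ny)];
              }
            }
          }
        }
        out[idx3(x, y, z, ox, oy)] = v;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// ---- marching-tetrahedra surface area -----------------------------------
// Area of the `level` iso-surface of a scalar field, with linearly
// interpolated edge crossings and a crack-free 6-tetrahedron cube
// decomposition. The field is implicitly zero-padded so the surface is
// closed.
static const int TETS[6][4] = {
  {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
};

inline double triarea(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double w0 = u[1]*v[2]-u[2]*v[1], w1 = u[2]*v[0]-u[0]*v[2],
         w2 = u[0]*v[1]-u[1]*v[0];
  return 0.5 * std::sqrt(w0*w0 + w1*w1 + w2*w2);
}

// [[Rcpp::export]]
double cpp_surface_area(NumericVector field, IntegerVector dim,
                        NumericVector spacing, double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double area = 0.0;
  // cells over padded grid: corner voxel indices -1 .. n-1
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double val[8]; double pos[8][3]; int any1 = 0, all1 = 1;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          double v = 0.0;
          if (inside(cx, cy, cz, nx, ny, nz))
            v = field[idx3(cx, cy, cz, nx, ny)];
          val[c] = v;
          if (v > level) any1 = 1; else all1 = 0;
          pos[c][0] = cx * spacing[0];
          pos[c][1] = cy * spacing[1];
          pos[c][2] = cz * spacing[2];
        }
        if (!any1 || all1) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in[4], nin = 0;
          for (int k = 0; k < 4; ++k) { in[k] = val[T[k]] > level; nin += in[k]; }
          if (nin == 0 || nin == 4) continue;
          // interpolated crossings on edges joining inside/outside vertices
          double pts[4][3]; int np = 0;
          for (int a = 0; a < 4; ++a)
            for (int b = a + 1; b < 4; ++b)
              if (in[a] != in[b]) {
                double t01 = (level - val[T[a]]) / (val[T[b]] - val[T[a]]);
                for (int d = 0; d < 3; ++d)
                  pts[np][d] = pos[T[a]][d] +
                    t01 * (pos[T[b]][d] - pos[T[a]][d]);
                ++np;
              }
          if (np == 3) {
            area += triarea(pts[0], pts[1], pts[2]);
          } else if (np == 4) {
            // quad: edges were enumerated (a,b) lexicographically; for the
            // 2-in/2-out case the crossing quad is pts[0],pts[1],pts[3],pts[2]
            area += triarea(pts[0], pts[1], pts[3]);
            area += triarea(pts[0], pts[3], pts[2]);
          }
        }
      }
  return area;
}

// ---- pairwise geometry helpers ------------------------------------------
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  int n = pts.nrow(), m = pts.ncol();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double t = pts(i, k) - pts(j, k);
        d += t * t;
      }
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// Min distance from each query point to a point set (both in mm).
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_set(NumericMatrix query, NumericMatrix set) {
  int n = query.nrow(), m = set.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = query(i,0) - set(j,0), dy = query(i,1) - set(j,1),
             dz = query(i,2) - set(j,2);
      double d = dx*dx + dy*dy + dz*dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
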