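// Compiled kernels: 3D connected components, 3x3x3 convolution, exact
// Euclidean distance transform, maximal-sphere local thickness, affine
// resampling, and a matrix-free conjugate-gradient solver for voxel
// hexahedral finite-element models.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static inline int64_t lin(int x, int y, int z, int nx, int ny) {
  return (int64_t)x + (int64_t)nx * ((int64_t)y + (int64_t)ny * (int64_t)z);
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6 or 26 connectivity), labels assigned in
// raster-scan order so the component containing the lowest linear voxel index
// gets label 1 (deterministic tie-breaks downstream).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int no = (int)dx.size();

  int next = 0;
  std::vector<int64_t> stack;
  for (int64_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int64_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((int64_t)nx * ny));
      for (int o = 0; o < no; ++o) {
        int xx = x + dx[o], yy = y + dy[o], zz = z + dz[o];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int64_t w = lin(xx, yy, zz, nx, ny);
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// 3x3x3 convolution with replicate (clamp) padding; kernel indexed
// (dx+1) + 3*(dy+1) + 9*(dz+1).
// [[Rcpp::export]]
NumericVector conv333_cpp(NumericVector img, IntegerVector dims,
                          NumericVector kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  NumericVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int cz = -1; cz <= 1; ++cz) {
          int zz = z + cz; if (zz < 0) zz = 0; if (zz >= nz) zz = nz - 1;
          for (int cy = -1; cy <= 1; ++cy) {
            int yy = y + cy; if (yy < 0) yy = 0; if (yy >= ny) yy = ny - 1;
            for (int cx = -1; cx <= 1; ++cx) {
              int xx = x + cx; if (xx < 0) xx = 0; if (xx >= nx) xx = nx - 1;
              acc += kernel[(cx + 1) + 3 * (cy + 1) + 9 * (cz + 1)] *
                     img[lin(xx, yy, zz, nx, ny)];
            }
          }
        }
        out[lin(x, y, z, nx, ny)] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance from each voxel to the nearest background (mask == 0) voxel
// centre, in voxel units. Background voxels get 0.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  const double INF = 1e30;
  NumericVector g(n);
  for (int64_t i = 0; i < n; ++i) g[i] = (mask[i] != 0) ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, v, zb, nx);
      for (int x = 0; x < nx; ++x) g[lin(x, y, z, nx, ny)] = d[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, v, zb, ny);
      for (int y = 0; y < ny; ++y) g[lin(x, y, z, nx, ny)] = d[y];
    }
  // along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, v, zb, nz);
      for (int z = 0; z < nz; ++z) g[lin(x, y, z, nx, ny)] = d[z];
    }
  g.attr("dim") = dims;
  return g;
}

// ---------------------------------------------------------------------------
// Maximal-sphere local thickness (Hildebrand-Rueegsegger): thickness(v) is
// the diameter of the largest sphere fully inside the foreground phase that
// contains v. A sphere centred at u with nearest-background distance d(u)
// has free radius d(u) - 0.5 (background voxel bodies are unit cubes), so it
// paints diameter 2*d(u) - 1 onto every voxel within that radius. Centres
// whose sphere is contained in a neighbour's sphere are skipped (distance
// ridge reduction); containment is checked with a conservative guard so the
// painted field is identical to the exhaustive all-centres computation.
// Output in voxel units; 0 on background.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  NumericVector d2 = edt_sq_cpp(mask, dims);
  NumericVector th(n, 0.0);

  std::vector<double> dt(n);
  for (int64_t i = 0; i < n; ++i) dt[i] = std::sqrt(d2[i]);

  // neighbour offsets for ridge test
  int ndx[26], ndy[26], ndz[26];
  double ndist[26];
  int no = 0;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        ndx[no] = cx; ndy[no] = cy; ndz[no] = cz;
        ndist[no] = std::sqrt((double)(cx * cx + cy * cy + cz * cz));
        ++no;
      }

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int64_t i = lin(x, y, z, nx, ny);
        if (mask[i] == 0) continue;
        double di = dt[i];
        // ridge reduction: skip if a neighbour's sphere surely contains ours
        bool skip = false;
        for (int o = 0; o < no; ++o) {
          int xx = x + ndx[o], yy = y + ndy[o], zz = z + ndz[o];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int64_t j = lin(xx, yy, zz, nx, ny);
          if (mask[j] != 0 && dt[j] >= di + ndist[o] + 1e-9) { skip = true; break; }
        }
        if (skip) continue;
        double rad2 = di * di;
        double diam = 2.0 * di - 1.0;
        int r = (int)std::floor(di);
        if (r < 0) r = 0;
        for (int cz = -r; cz <= r; ++cz) {
          int zz = z + cz; if (zz < 0 || zz >= nz) continue;
          for (int cy = -r; cy <= r; ++cy) {
            int yy = y + cy; if (yy < 0 || yy >= ny) continue;
            for (int cx = -r; cx <= r; ++cx) {
              int xx = x + cx; if (xx < 0 || xx >= nx) continue;
              double dd = (double)(cx * cx + cy * cy + cz * cz);
              if (dd <= rad2) {
                int64_t j = lin(xx, yy, zz, nx, ny);
                if (mask[j] != 0 && diam > th[j]) th[j] = diam;
              }
            }
          }
        }
      }
  // every foreground voxel is at least its own unit cube
  for (int64_t i = 0; i < n; ++i)
    if (mask[i] != 0 && th[i] < 1.0) th[i] = 1.0;
  th.attr("dim") = dims;
  return th;
}

// ---------------------------------------------------------------------------
// Affine resampling: out(i,j,k) = img(A %*% c(i,j,k,1)), 0-based voxel
// coordinates; method 0 = nearest neighbour, 1 = trilinear.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector img, IntegerVector dims,
                                  NumericMatrix A, IntegerVector out_dims,
                                  int method, double background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((int64_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double sx = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double sy = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double sz = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        double val = background;
        if (method == 0) {
          int rx = (int)std::lround(sx), ry = (int)std::lround(sy),
              rz = (int)std::lround(sz);
          if (rx >= 0 && ry >= 0 && rz >= 0 && rx < nx && ry < ny && rz < nz)
            val = img[lin(rx, ry, rz, nx, ny)];
        } else {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
              z0 = (int)std::floor(sz);
          double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          if (x0 >= 0 && y0 >= 0 && z0 >= 0 && x0 + 1 < nx && y0 + 1 < ny &&
              z0 + 1 < nz) {
            double c00 = img[lin(x0, y0, z0, nx, ny)] * (1 - fx) +
                         img[lin(x0 + 1, y0, z0, nx, ny)] * fx;
            double c10 = img[lin(x0, y0 + 1, z0, nx, ny)] * (1 - fx) +
                         img[lin(x0 + 1, y0 + 1, z0, nx, ny)] * fx;
            double c01 = img[lin(x0, y0, z0 + 1, nx, ny)] * (1 - fx) +
                         img[lin(x0 + 1, y0, z0 + 1, nx, ny)] * fx;
            double c11 = img[lin(x0, y0 + 1, z0 + 1, nx, ny)] * (1 - fx) +
                         img[lin(x0 + 1, y0 + 1, z0 + 1, nx, ny)] * fx;
            val = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                  (c01 * (1 - fy) + c11 * fy) * fz;
          }
        }
        out[lin(i, j, k, ox, oy)] = val;
      }
  out.attr("dim") = out_dims;
  return out;
}

// ---------------------------------------------------------------------------
// Matrix-free hexahedral FE. All elements share one 24x24 stiffness Ke
// (uniform cube edge). DOF ordering: node n -> (3n, 3n+1, 3n+2) = (x,y,z).

static void fe_matvec(const IntegerMatrix &elems, const double *Ke,
                      const double *x, double *y, int64_t ndof) {
  for (int64_t i = 0; i < ndof; ++i) y[i] = 0.0;
  const int ne = elems.nrow();
  double ue[24], fe[24];
  for (int e = 0; e < ne; ++e) {
    int dof[24];
    for (int a = 0; a < 8; ++a) {
      int nnode = elems(e, a);
      dof[3 * a] = 3 * nnode;
      dof[3 * a + 1] = 3 * nnode + 1;
      dof[3 * a + 2] = 3 * nnode + 2;
    }
    for (int a = 0; a < 24; ++a) ue[a] = x[dof[a]];
    for (int a = 0; a < 24; ++a) {
      double acc = 0.0;
      const double *col = Ke + 24 * a; // Ke column-major, symmetric
      for (int b = 0; b < 24; ++b) acc += col[b] * ue[b];
      fe[a] = acc;
    }
    for (int a = 0; a < 24; ++a) y[dof[a]] += fe[a];
  }
}

// [[Rcpp::export]]
List fe_cg_cpp(IntegerMatrix elems, int nnodes, NumericMatrix Ke,
               NumericVector fixed, NumericVector f, double rtol,
               int maxit) {
  const int64_t ndof = (int64_t)3 * nnodes;
  std::vector<double> KeV(576);
  for (int j = 0; j < 24; ++j)
    for (int i = 0; i < 24; ++i) KeV[i + 24 * j] = Ke(i, j);

  std::vector<uint8_t> isfix(ndof, 0);
  std::vector<double> u(ndof, 0.0);
  for (int64_t i = 0; i < ndof; ++i) {
    if (!NumericVector::is_na(fixed[i])) {
      isfix[i] = 1;
      u[i] = fixed[i];
    }
  }

  // Jacobi diagonal on free dofs
  std::vector<double> diag(ndof, 0.0);
  const int ne = elems.nrow();
  for (int e = 0; e < ne; ++e)
    for (int a = 0; a < 8; ++a) {
      int nnode = elems(e, a);
      for (int c = 0; c < 3; ++c)
        diag[3 * nnode + c] += KeV[(3 * a + c) + 24 * (3 * a + c)];
    }

  // rhs = f - K u_c on free dofs
  std::vector<double> tmp(ndof), b(ndof, 0.0);
  fe_matvec(elems, KeV.data(), u.data(), tmp.data(), ndof);
  double bnorm2 = 0.0;
  for (int64_t i = 0; i < ndof; ++i) {
    if (!isfix[i]) {
      b[i] = f[i] - tmp[i];
      bnorm2 += b[i] * b[i];
    }
  }
  double bnorm = std::sqrt(bnorm2);
  if (bnorm == 0.0) bnorm = 1.0;

  std::vector<double> x(ndof, 0.0), r(b), z(ndof, 0.0), p(ndof, 0.0),
      Ap(ndof, 0.0);
  double rz = 0.0;
  for (int64_t i = 0; i < ndof; ++i) {
    if (!isfix[i]) {
      z[i] = r[i] / diag[i];
      p[i] = z[i];
      rz += r[i] * z[i];
    }
  }
  int it = 0;
  double relres = 1.0;
  for (; it < maxit; ++it) {
    double rn2 = 0.0;
    for (int64_t i = 0; i < ndof; ++i)
      if (!isfix[i]) rn2 += r[i] * r[i];
    relres = std::sqrt(rn2) / bnorm;
    if (relres <= rtol) break;
    fe_matvec(elems, KeV.data(), p.data(), Ap.data(), ndof);
    double pAp = 0.0;
    for (int64_t i = 0; i < ndof; ++i)
      if (!isfix[i]) pAp += p[i] * Ap[i];
    double alpha = rz / pAp;
    for (int64_t i = 0; i < ndof; ++i) {
      if (!isfix[i]) {
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
      }
    }
    double rznew = 0.0;
    for (int64_t i = 0; i < ndof; ++i) {
      if (!isfix[i]) {
        z[i] = r[i] / diag[i];
        rznew += r[i] * z[i];
      }
    }
    double beta = rznew / rz;
    rz = rznew;
    for (int64_t i = 0; i < ndof; ++i)
      if (!isfix[i]) p[i] = z[i] + beta * p[i];
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector uout(ndof);
  for (int64_t i = 0; i < ndof; ++i) uout[i] = isfix[i] ? u[i] : x[i];
  return List::create(_["u"] = uout, _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = (relres <= rtol));
}

// [[Rcpp::export]]
NumericVector fe_forces_cpp(IntegerMatrix elems, int nnodes, NumericMatrix Ke,
                            NumericVector u) {
  const int64_t ndof = (int64_t)3 * nnodes;
  std::vector<double> KeV(576);
  for (int j = 0; j < 24; ++j)
    for (int i = 0; i < 24; ++i) KeV[i + 24 * j] = Ke(i, j);
  NumericVector out(ndof);
  std::vector<double> y(ndof);
  std::vector<double> x(u.begin(), u.end());
  fe_matvec(elems, KeV.data(), x.data(), y.data(), ndof);
  for (int64_t i = 0; i < ndof; ++i) out[i] = y[i];
  return out;
}

// Per-node strain tensors: element centroid strain eps = Bc %*% u_e,
// volume-averaged over the elements adjacent to each node (uniform element
// volume -> arithmetic mean). Returns nnodes x 6 (xx, yy, zz, gxy, gyz, gxz).
// [[Rcpp::export]]
NumericMatrix fe_nodal_strains_cpp(IntegerMatrix elems, int nnodes,
                                   NumericMatrix Bc, NumericVector u) {
  NumericMatrix out(nnodes, 6);
  std::vector<int> cnt(nnodes, 0);
  const int ne = elems.nrow();
  double ue[24], eps[6];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 8; ++a) {
      int nnode = elems(e, a);
      ue[3 * a] = u[3 * nnode];
      ue[3 * a + 1] = u[3 * nnode + 1];
      ue[3 * a + 2] = u[3 * nnode + 2];
    }
    for (int r = 0; r < 6; ++r) {
      double acc = 0.0;
      for (int c = 0; c < 24; ++c) acc += Bc(r, c) * ue[c];
      eps[r] = acc;
    }
    for (int a = 0; a < 8; ++a) {
      int nnode = elems(e, a);
      cnt[nnode]++;
      for (int r = 0; r < 6; ++r) out(nnode, r) += eps[r];
    }
  }
  for (int i = 0; i < nnodes; ++i)
    if (cnt[i] > 0)
      for (int r = 0; r < 6; ++r) out(i, r) /= cnt[i];
  return out;
}

// Principal strains (descending) of symmetric tensors given as rows
// (xx, yy, zz, gxy, gyz, gxz) with engineering shear.
// [[Rcpp::export]]
NumericMatrix principal_strains_cpp(NumericMatrix eps) {
  const int n = eps.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double a11 = eps(i, 0), a22 = eps(i, 1), a33 = eps(i, 2);
    double a12 = 0.5 * eps(i, 3), a23 = 0.5 * eps(i, 4), a13 = 0.5 * eps(i, 5);
    double p1 = a12 * a12 + a13 * a13 + a23 * a23;
    double e1, e2, e3;
    if (p1 < 1e-300) {
      e1 = a11; e2 = a22; e3 = a33;
      if (e1 < e2) std::swap(e1, e2);
      if (e2 < e3) std::swap(e2, e3);
      if (e1 < e2) std::swap(e1, e2);
    } else {
      double q = (a11 + a22 + a33) / 3.0;
      double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                  (a33 - q) * (a33 - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
      double b12 = a12 / p, b23 = a23 / p, b13 = a13 / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e2 = 3.0 * q - e1 - e3;
    }
    out(i, 0) = e1;
    out(i, 1) = e2;
    out(i, 2) = e3;
  }
  return out;
}
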