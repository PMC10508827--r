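#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Linear index for a 0-based (i,j,k) voxel in an R column-major array.
static inline R_xlen_t lidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Per-centre block intensity mean and variance (two-pass, block half-extent B).
// centers0: n x 3 matrix of 0-based voxel indices; caller guarantees in-bounds.
// [[Rcpp::export]]
NumericMatrix cpp_block_variance(NumericVector img, IntegerVector dim,
                                 IntegerVector B, IntegerMatrix centers0) {
  const int nx = dim[0], ny = dim[1];
  const int bx = B[0], by = B[1], bz = B[2];
  const int n = centers0.nrow();
  const double nvox = (double)(2 * bx + 1) * (2 * by + 1) * (2 * bz + 1);
  NumericMatrix out(n, 2);
  for (int p = 0; p < n; ++p) {
    const int ci = centers0(p, 0), cj = centers0(p, 1), ck = centers0(p, 2);
    double s = 0.0;
    for (int k = ck - bz; k <= ck + bz; ++k)
      for (int j = cj - by; j <= cj + by; ++j)
        for (int i = ci - bx; i <= ci + bx; ++i)
          s += img[lidx(i, j, k, nx, ny)];
    const double mean = s / nvox;
    double ss = 0.0;
    for (int k = ck - bz; k <= ck + bz; ++k)
      for (int j = cj - by; j <= cj + by; ++j)
        for (int i = ci - bx; i <= ci + bx; ++i) {
          const double d = img[lidx(i, j, k, nx, ny)] - mean;
          ss += d * d;
        }
    out(p, 0) = mean;
    out(p, 1) = ss / (nvox - 1.0);
  }
  return out;
}

// Exhaustive integer-voxel block matching with NCC.
// Returns n x 6: dx, dy, dz (voxels), best NCC, number of NCC evaluations,
// degenerate flag (1 = no defined NCC anywhere, match must be dropped).
// Tie-break: higher NCC, then smaller |d|^2, then lexicographic (dz, dy, dx).
// [[Rcpp::export]]
NumericMatrix cpp_block_match(NumericVector flt, NumericVector fix,
                              IntegerVector dim, IntegerVector B,
                              IntegerVector W, IntegerMatrix centers0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int bx = B[0], by = B[1], bz = B[2];
  const int wx = W[0], wy = W[1], wz = W[2];
  const int n = centers0.nrow();
  const int bn = (2 * bx + 1) * (2 * by + 1) * (2 * bz + 1);
  NumericMatrix out(n, 6);
  std::vector<double> blk(bn);
  for (int p = 0; p < n; ++p) {
    const int ci = centers0(p, 0), cj = centers0(p, 1), ck = centers0(p, 2);
    // centred floating block
    double s = 0.0;
    int t = 0;
    for (int k = ck - bz; k <= ck + bz; ++k)
      for (int j = cj - by; j <= cj + by; ++j)
        for (int i = ci - bx; i <= ci + bx; ++i)
          s += (blk[t++] = flt[lidx(i, j, k, nx, ny)]);
    const double amean = s / bn;
    double anorm2 = 0.0;
    for (t = 0; t < bn; ++t) {
      blk[t] -= amean;
      anorm2 += blk[t] * blk[t];
    }
    const bool flt_const = (anorm2 <= 0.0);
    double best = -2.0, bestn2 = 0.0;
    int bdx = 0, bdy = 0, bdz = 0;
    long nev = 0;
    bool any_defined = false;
    for (int dz = -wz; dz <= wz; ++dz)
      for (int dy = -wy; dy <= wy; ++dy)
        for (int dx = -wx; dx <= wx; ++dx) {
          ++nev;
          const int oi = ci + dx, oj = cj + dy, ok = ck + dz;
          if (oi - bx < 0 || oj - by < 0 || ok - bz < 0 ||
              oi + bx >= nx || oj + by >= ny || ok + bz >= nz)
            continue;  // block would leave the fixed image
          if (flt_const) continue;
          double bs = 0.0;
          for (int k = ok - bz; k <= ok + bz; ++k)
            for (int j = oj - by; j <= oj + by; ++j)
              for (int i = oi - bx; i <= oi + bx; ++i)
                bs += fix[lidx(i, j, k, nx, ny)];
          const double bmean = bs / bn;
          double dot = 0.0, bnorm2 = 0.0;
          t = 0;
          for (int k = ok - bz; k <= ok + bz; ++k)
            for (int j = oj - by; j <= oj + by; ++j)
              for (int i = oi - bx; i <= oi + bx; ++i) {
                const double bv = fix[lidx(i, j, k, nx, ny)] - bmean;
                dot += blk[t++] * bv;
                bnorm2 += bv * bv;
              }
          if (bnorm2 <= 0.0) continue;  // undefined NCC in the fixed window
          double c = dot / std::sqrt(anorm2 * bnorm2);
          if (c > 1.0) c = 1.0;
          if (c < -1.0) c = -1.0;
          any_defined = true;
          const double n2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
          bool take = false;
          if (c > best) take = true;
          else if (c == best) {
            if (n2 < bestn2) take = true;
            else if (n2 == bestn2) {
              if (dz < bdz || (dz == bdz && (dy < bdy || (dy == bdy && dx < bdx))))
                take = true;
            }
          }
          if (take) { best = c; bestn2 = n2; bdx = dx; bdy = dy; bdz = dz; }
        }
    out(p, 0) = bdx; out(p, 1) = bdy; out(p, 2) = bdz;
    out(p, 3) = any_defined ? best : 0.0;
    out(p, 4) = (double)nev;
    out(p, 5) = any_defined ? 0.0 : 1.0;
  }
  return out;
}

struct TetGeom {
  double ax, ay, az;      // vertex a
  double inv[9];          // inverse of [b-a c-a d-a] (column-major 3x3)
  double lo[3], hi[3];    // bounding box
  bool ok;
};

static std::vector<TetGeom> tet_geoms(const NumericMatrix &V,
                                      const IntegerMatrix &T) {
  const int M = T.nrow();
  std::vector<TetGeom> G(M);
  for (int e = 0; e < M; ++e) {
    TetGeom g;
    const int a = T(e, 0), b = T(e, 1), c = T(e, 2), d = T(e, 3);
    g.ax = V(a, 0); g.ay = V(a, 1); g.az = V(a, 2);
    double m[9] = {
      V(b, 0) - g.ax, V(b, 1) - g.ay, V(b, 2) - g.az,
      V(c, 0) - g.ax, V(c, 1) - g.ay, V(c, 2) - g.az,
      V(d, 0) - g.ax, V(d, 1) - g.ay, V(d, 2) - g.az};
    const double det =
      m[0] * (m[4] * m[8] - m[5] * m[7]) -
      m[3] * (m[1] * m[8] - m[2] * m[7]) +
      m[6] * (m[1] * m[5] - m[2] * m[4]);
    g.ok = std::abs(det) > 1e-300;
    if (g.ok) {
      const double id = 1.0 / det;
      g.inv[0] = (m[4] * m[8] - m[5] * m[7]) * id;
      g.inv[1] = (m[2] * m[7] - m[1] * m[8]) * id;
      g.inv[2] = (m[1] * m[5] - m[2] * m[4]) * id;
      g.inv[3] = (m[5] * m[6] - m[3] * m[8]) * id;
      g.inv[4] = (m[0] * m[8] - m[2] * m[6]) * id;
      g.inv[5] = (m[2] * m[3] - m[0] * m[5]) * id;
      g.inv[6] = (m[3] * m[7] - m[4] * m[6]) * id;
      g.inv[7] = (m[1] * m[6] - m[0] * m[7]) * id;
      g.inv[8] = (m[0] * m[4] - m[1] * m[3]) * id;
    }
    for (int ax = 0; ax < 3; ++ax) {
      double lo = V(a, ax), hi = lo;
      for (int vv = 1; vv < 4; ++vv) {
        const double x = V(T(e, vv), ax);
        if (x < lo) lo = x;
        if (x > hi) hi = x;
      }
      g.lo[ax] = lo; g.hi[ax] = hi;
    }
    G[e] = g;
  }
  return G;
}

static inline void bary_of(const TetGeom &g, double x, double y, double z,
                           double w[4]) {
  const double px = x - g.ax, py = y - g.ay, pz = z - g.az;
  const double w1 = g.inv[0] * px + g.inv[3] * py + g.inv[6] * pz;
  const double w2 = g.inv[1] * px + g.inv[4] * py + g.inv[7] * pz;
  const double w3 = g.inv[2] * px + g.inv[5] * py + g.inv[8] * pz;
  w[0] = 1.0 - w1 - w2 - w3; w[1] = w1; w[2] = w2; w[3] = w3;
}

// Locate world points in a tet mesh. Returns n x 5: 0-based containing tet
// (or -1) and the four barycentric weights. Tolerance: weights >= -tol.
// Ties (shared faces) resolve to the lowest tet index.
// [[Rcpp::export]]
NumericMatrix cpp_locate_points(NumericMatrix V, IntegerMatrix T,
                                NumericMatrix P, double tol) {
  const int M = T.nrow(), n = P.nrow();
  std::vector<TetGeom> G = tet_geoms(V, T);
  NumericMatrix out(n, 5);
  double w[4];
  for (int p = 0; p < n; ++p) {
    const double x = P(p, 0), y = P(p, 1), z = P(p, 2);
    int found = -1;
    for (int e = 0; e < M; ++e) {
      const TetGeom &g = G[e];
      if (!g.ok) continue;
      if (x < g.lo[0] - tol || x > g.hi[0] + tol ||
          y < g.lo[1] - tol || y > g.hi[1] + tol ||
          z < g.lo[2] - tol || z > g.hi[2] + tol) continue;
      bary_of(g, x, y, z, w);
      if (w[0] >= -tol && w[1] >= -tol && w[2] >= -tol && w[3] >= -tol) {
        found = e;
        break;
      }
    }
    out(p, 0) = found;
    if (found >= 0) {
      for (int q = 0; q < 4; ++q) out(p, q + 1) = w[q];
    } else {
      for (int q = 0; q < 4; ++q) out(p, q + 1) = 0.0;
    }
  }
  return out;
}

// Rasterise a nodal displacement field to a dense grid. Returns nvox x 4 in
// image linear order: ux, uy, uz and an inside-mesh flag.
// [[Rcpp::export]]
NumericMatrix cpp_nodal_to_dense(NumericMatrix V, IntegerMatrix T,
                                 NumericMatrix U, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int M = T.nrow();
  std::vector<TetGeom> G = tet_geoms(V, T);
  NumericMatrix out((R_xlen_t)nx * ny * nz, 4);
  double w[4];
  const double tol = 1e-9;
  for (int e = 0; e < M; ++e) {
    const TetGeom &g = G[e];
    if (!g.ok) continue;
    int ilo[3], ihi[3];
    bool empty = false;
    for (int ax = 0; ax < 3; ++ax) {
      const int nax = (ax == 0) ? nx : (ax == 1 ? ny : nz);
      int lo = (int)std::ceil((g.lo[ax] - origin[ax]) / spacing[ax] - 1e-9);
      int hi = (int)std::floor((g.hi[ax] - origin[ax]) / spacing[ax] + 1e-9);
      if (lo < 0) lo = 0;
      if (hi > nax - 1) hi = nax - 1;
      if (lo > hi) empty = true;
      ilo[ax] = lo; ihi[ax] = hi;
    }
    if (empty) continue;
    for (int k = ilo[2]; k <= ihi[2]; ++k)
      for (int j = ilo[1]; j <= ihi[1]; ++j)
        for (int i = ilo[0]; i <= ihi[0]; ++i) {
          const double x = origin[0] + i * spacing[0];
          const double y = origin[1] + j * spacing[1];
          const double z = origin[2] + k * spacing[2];
          bary_of(g, x, y, z, w);
          if (w[0] < -tol || w[1] < -tol || w[2] < -tol || w[3] < -tol)
            continue;
          const R_xlen_t li = lidx(i, j, k, nx, ny);
          for (int ax = 0; ax < 3; ++ax) {
            double u = 0.0;
            for (int q = 0; q < 4; ++q) u += w[q] * U(T(e, q), ax);
            out(li, ax) = u;
          }
          out(li, 3) = 1.0;
        }
  }
  return out;
}

// One step of 6-neighbour mean extrapolation of a partial vector field:
// unfilled voxels adjacent to filled ones get the mean of their filled
// neighbours. Modifies nothing; returns the grown nvox x 4 field.
// [[Rcpp::export]]
NumericMatrix cpp_extend_field(NumericMatrix u, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out = clone(u);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t li = lidx(i, j, k, nx, ny);
        if (u(li, 3) != 0.0) continue;
        double acc[3] = {0, 0, 0};
        int cnt = 0;
        for (int q = 0; q < 6; ++q) {
          const int ii = i + off[q][0], jj = j + off[q][1],
                    kk = k + off[q][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
              kk >= nz)
            continue;
          const R_xlen_t lj = lidx(ii, jj, kk, nx, ny);
          if (u(lj, 3) != 0.0) {
            for (int ax = 0; ax < 3; ++ax) acc[ax] += u(lj, ax);
            ++cnt;
          }
        }
        if (cnt > 0) {
          for (int ax = 0; ax < 3; ++ax) out(li, ax) = acc[ax] / cnt;
          out(li, 3) = 1.0;
        }
      }
  return out;
}

static inline double sample_trilinear(const NumericVector &img, int nx, int ny,
                                      int nz, double fi, double fj, double fk) {
  const int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj),
            k0 = (int)std::floor(fk);
  const double di = fi - i0, dj = fj - j0, dk = fk - k0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        const int i = i0 + dx, j = j0 + dy, k = k0 + dz;
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
          continue;  // out-of-bounds corners contribute 0
        const double wgt = (dx ? di : 1.0 - di) * (dy ? dj : 1.0 - dj) *
                           (dz ? dk : 1.0 - dk);
        acc += wgt * img[lidx(i, j, k, nx, ny)];
      }
  return acc;
}

// Backward warp: out(x) = img(x - u(x)). order 0 = nearest, 1 = trilinear.
// Displacements are in mm on the output grid; out-of-bounds samples are 0.
// [[Rcpp::export]]
NumericVector cpp_warp_image(NumericVector img, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericMatrix u, int order) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t li = lidx(i, j, k, nx, ny);
        const double fi = i - u(li, 0) / spacing[0];
        const double fj = j - u(li, 1) / spacing[1];
        const double fk = k - u(li, 2) / spacing[2];
        if (order == 0) {
          const int ri = (int)std::floor(fi + 0.5);
          const int rj = (int)std::floor(fj + 0.5);
          const int rk = (int)std::floor(fk + 0.5);
          out[li] = (ri < 0 || rj < 0 || rk < 0 || ri >= nx || rj >= ny ||
                     rk >= nz)
                        ? 0.0
                        : img[lidx(ri, rj, rk, nx, ny)];
        } else {
          out[li] = sample_trilinear(img, nx, ny, nz, fi, fj, fk);
        }
      }
  return out;
}

// Separable Gaussian smoothing, kernels truncated at 3 sigma and
// renormalised at the borders. sigma given in voxels per axis; sigma <= 0
// skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector img, IntegerVector dim,
                               NumericVector sigma) {
  const int nd[3] = {dim[0], dim[1], dim[2]};
  std::vector<double> cur(img.begin(), img.end());
  std::vector<double> nxt(cur.size());
  const int nx = nd[0], ny = nd[1];
  for (int ax = 0; ax < 3; ++ax) {
    const double sg = sigma[ax];
    if (sg <= 0.0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * sg));
    std::vector<double> ker(2 * r + 1);
    for (int t = -r; t <= r; ++t)
      ker[t + r] = std::exp(-0.5 * (double)t * t / (sg * sg));
    const int n = nd[ax];
    for (int k = 0; k < nd[2]; ++k)
      for (int j = 0; j < nd[1]; ++j)
        for (int i = 0; i < nd[0]; ++i) {
          const int pos = (ax == 0) ? i : (ax == 1 ? j : k);
          double acc = 0.0, wsum = 0.0;
          for (int t = -r; t <= r; ++t) {
            const int q = pos + t;
            if (q < 0 || q >= n) continue;
            const double w = ker[t + r];
            wsum += w;
            const int ii = (ax == 0) ? q : i;
            const int jj = (ax == 1) ? q : j;
            const int kk = (ax == 2) ? q : k;
            acc += w * cur[lidx(ii, jj, kk, nx, ny)];
          }
          nxt[lidx(i, j, k, nx, ny)] = acc / wsum;
        }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

// Non-maximum suppression along the local gradient direction (unit step in
// voxel units, trilinear magnitude sampling). Gradients are in world (mm)
// units and get rescaled by spacing to index space.
// [[Rcpp::export]]
LogicalVector cpp_canny_nms(NumericVector mag, NumericVector gx,
                            NumericVector gy, NumericVector gz,
                            IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector keep((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t li = lidx(i, j, k, nx, ny);
        const double m = mag[li];
        if (m <= 0.0) { keep[li] = false; continue; }
        double di = gx[li] / spacing[0], dj = gy[li] / spacing[1],
               dk = gz[li] / spacing[2];
        const double nn = std::sqrt(di * di + dj * dj + dk * dk);
        if (nn <= 0.0) { keep[li] = false; continue; }
        di /= nn; dj /= nn; dk /= nn;
        const double m1 =
            sample_trilinear(mag, nx, ny, nz, i + di, j + dj, k + dk);
        const double m2 =
            sample_trilinear(mag, nx, ny, nz, i - di, j - dj, k - dk);
        keep[li] = (m >= m1 && m >= m2);
      }
  return keep;
}

// Hysteresis: BFS from strong voxels through candidate voxels
// (26-connectivity).
// [[Rcpp::export]]
LogicalVector cpp_hysteresis(LogicalVector strong, LogicalVector cand,
                             IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::queue<R_xlen_t> q;
  for (R_xlen_t li = 0; li < out.size(); ++li)
    if (strong[li]) { out[li] = true; q.push(li); }
  while (!q.empty()) {
    const R_xlen_t li = q.front(); q.pop();
    const int i = (int)(li % nx);
    const int j = (int)((li / nx) % ny);
    const int k = (int)(li / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const R_xlen_t lj = lidx(ii, jj, kk, nx, ny);
          if (cand[lj] && !out[lj]) { out[lj] = true; q.push(lj); }
        }
  }
  return out;
}

// For each row of A, the minimum Euclidean distance to the rows of B.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
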