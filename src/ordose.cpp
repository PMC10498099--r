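// Transport kernels: radiological-depth ray integration and the
// discrete-ordinates transport sweep with the hybrid diamond/step closure.
//
// Grids are column-major I x J x K with voxel-corner origin.  The sweep
// solves, per ordinate and energy group,
//   phi_c = (2|mu|/dx phi_in_x + 2|eta|/dy phi_in_y + 2|xi|/dz phi_in_z + Q)
//           / (2|mu|/dx + 2|eta|/dy + 2|xi|/dz + sigma)
// with the outflow faces set equal to the centre value (step closure), so
// the upwind inflow of a voxel is simply the centre value of its upwind
// neighbour and a single octant-ordered pass solves the group exactly for
// fixed sources.  Boundary condition: vacuum (zero inflow).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int I, int J) {
  return i + I * (j + J * k);
}

// [[Rcpp::export]]
NumericVector cpp_radiological_depth(NumericVector rho, IntegerVector dims,
                                     NumericVector spacing,
                                     NumericVector src, NumericMatrix pts,
                                     double step) {
  const int I = dims[0], J = dims[1], K = dims[2];
  const double ex = I * spacing[0], ey = J * spacing[1], ez = K * spacing[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double dx = pts(q, 0) - src[0], dy = pts(q, 1) - src[1],
           dz = pts(q, 2) - src[2];
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0) { out[q] = 0; continue; }
    dx /= L; dy /= L; dz /= L;
    // entry parameter into the grid box via the slab method
    double t0 = 0.0, t1 = L;
    const double o[3] = { src[0], src[1], src[2] };
    const double d[3] = { dx, dy, dz };
    const double hi[3] = { ex, ey, ez };
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (o[a] < 0 || o[a] > hi[a]) { miss = true; break; }
      } else {
        double ta = (0.0 - o[a]) / d[a], tb = (hi[a] - o[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    if (miss || t1 <= t0) { out[q] = 0; continue; }
    double acc = 0.0;
    int nstep = (int)std::ceil((t1 - t0) / step);
    double h = (t1 - t0) / nstep;
    for (int s = 0; s < nstep; ++s) {
      double t = t0 + (s + 0.5) * h;
      int i = (int)std::floor((o[0] + t * d[0]) / spacing[0]);
      int j = (int)std::floor((o[1] + t * d[1]) / spacing[1]);
      int k = (int)std::floor((o[2] + t * d[2]) / spacing[2]);
      if (i < 0) i = 0; if (i >= I) i = I - 1;
      if (j < 0) j = 0; if (j >= J) j = J - 1;
      if (k < 0) k = 0; if (k >= K) k = K - 1;
      acc += rho[idx3(i, j, k, I, J)] * h;
    }
    out[q] = acc;
  }
  return out;
}

// Sweep all ordinates of one energy group.  Q: N x V scatter+fixed source;
// sigma: V macroscopic removal (1/mm); dirs: N x 3 direction cosines.
// Returns the centre fluence, N x V.
// [[Rcpp::export]]
NumericMatrix cpp_sweep_group(NumericMatrix Q, NumericVector sigma,
                              IntegerVector dims, NumericVector spacing,
                              NumericMatrix dirs) {
  const int I = dims[0], J = dims[1], K = dims[2];
  const int N = dirs.nrow();
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  NumericMatrix phi(N, (R_xlen_t)I * J * K);
  for (int n = 0; n < N; ++n) {
    const double mu = dirs(n, 0), eta = dirs(n, 1), xi = dirs(n, 2);
    const double ax = 2.0 * std::fabs(mu) / dx;
    const double ay = 2.0 * std::fabs(eta) / dy;
    const double az = 2.0 * std::fabs(xi) / dz;
    if (ax + ay + az <= 0) stop("all three direction cosines are zero");
    const int si = mu >= 0 ? 1 : -1, sj = eta >= 0 ? 1 : -1,
              sk = xi >= 0 ? 1 : -1;
    const int i0 = si > 0 ? 0 : I - 1, j0 = sj > 0 ? 0 : J - 1,
              k0 = sk > 0 ? 0 : K - 1;
    for (int kk = 0; kk < K; ++kk) {
      const int k = k0 + sk * kk;
      for (int jj = 0; jj < J; ++jj) {
        const int j = j0 + sj * jj;
        for (int ii = 0; ii < I; ++ii) {
          const int i = i0 + si * ii;
          const R_xlen_t v = idx3(i, j, k, I, J);
          double num = Q(n, v);
          if (ax > 0 && ii > 0) num += ax * phi(n, idx3(i - si, j, k, I, J));
          if (ay > 0 && jj > 0) num += ay * phi(n, idx3(i, j - sj, k, I, J));
          if (az > 0 && kk > 0) num += az * phi(n, idx3(i, j, k - sk, I, J));
          phi(n, v) = num / (ax + ay + az + sigma[v]);
        }
      }
    }
  }
  return phi;
}

// Adaptive variant: 4x4x4 clusters flagged in `merged` (column-major over
// supercells of size scI x scJ x scK) are treated as single 4*d voxels:
// inflow is the mean of the 16 abutting upstream face (centre) values, the
// source and removal are cluster means, and the single centre value is
// replicated to all 64 member voxels (so downstream outflow replication is
// automatic under the step closure).
// [[Rcpp::export]]
NumericMatrix cpp_sweep_group_adaptive(NumericMatrix Q, NumericVector sigma,
                                       IntegerVector dims,
                                       NumericVector spacing,
                                       NumericMatrix dirs,
                                       LogicalVector merged,
                                       IntegerVector scdims) {
  const int I = dims[0], J = dims[1], K = dims[2];
  const int N = dirs.nrow();
  const int SI = scdims[0], SJ = scdims[1], SK = scdims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  NumericMatrix phi(N, (R_xlen_t)I * J * K);
  for (int n = 0; n < N; ++n) {
    const double mu = dirs(n, 0), eta = dirs(n, 1), xi = dirs(n, 2);
    const double ax = 2.0 * std::fabs(mu) / dx;
    const double ay = 2.0 * std::fabs(eta) / dy;
    const double az = 2.0 * std::fabs(xi) / dz;
    const double AX = ax / 4.0, AY = ay / 4.0, AZ = az / 4.0; // merged cell
    if (ax + ay + az <= 0) stop("all three direction cosines are zero");
    const int si = mu >= 0 ? 1 : -1, sj = eta >= 0 ? 1 : -1,
              sk = xi >= 0 ? 1 : -1;
    const int s0 = si > 0 ? 0 : SI - 1, t0 = sj > 0 ? 0 : SJ - 1,
              u0 = sk > 0 ? 0 : SK - 1;
    for (int uu = 0; uu < SK; ++uu) {
      const int sc_k = u0 + sk * uu;
      for (int tt = 0; tt < SJ; ++tt) {
        const int sc_j = t0 + sj * tt;
        for (int ss = 0; ss < SI; ++ss) {
          const int sc_i = s0 + si * ss;
          const int ia = sc_i * 4, ja = sc_j * 4, ka = sc_k * 4;
          const bool is_merged =
            merged[sc_i + SI * (sc_j + SJ * sc_k)] &&
            ia + 4 <= I && ja + 4 <= J && ka + 4 <= K;
          if (is_merged) {
            // upstream faces of the merged cell
            double inx = 0, iny = 0, inz = 0;
            const int ifc = si > 0 ? ia : ia + 3;      // upwind layer index
            const int jfc = sj > 0 ? ja : ja + 3;
            const int kfc = sk > 0 ? ka : ka + 3;
            if (ax > 0 && ((si > 0 && ia > 0) || (si < 0 && ia + 4 < I))) {
              for (int j = ja; j < ja + 4; ++j)
                for (int k = ka; k < ka + 4; ++k)
                  inx += phi(n, idx3(ifc - si, j, k, I, J));
              inx /= 16.0;
            }
            if (ay > 0 && ((sj > 0 && ja > 0) || (sj < 0 && ja + 4 < J))) {
              for (int i = ia; i < ia + 4; ++i)
                for (int k = ka; k < ka + 4; ++k)
                  iny += phi(n, idx3(i, jfc - sj, k, I, J));
              iny /= 16.0;
            }
            if (az > 0 && ((sk > 0 && ka > 0) || (sk < 0 && ka + 4 < K))) {
              for (int i = ia; i < ia + 4; ++i)
                for (int j = ja; j < ja + 4; ++j)
                  inz += phi(n, idx3(i, j, kfc - sk, I, J));
              inz /= 16.0;
            }
            double qbar = 0, sbar = 0;
            for (int k = ka; k < ka + 4; ++k)
              for (int j = ja; j < ja + 4; ++j)
                for (int i = ia; i < ia + 4; ++i) {
                  const R_xlen_t v = idx3(i, j, k, I, J);
                  qbar += Q(n, v); sbar += sigma[v];
                }
            qbar /= 64.0; sbar /= 64.0;
            const double val = (AX * inx + AY * iny + AZ * inz + qbar) /
                               (AX + AY + AZ + sbar);
            for (int k = ka; k < ka + 4; ++k)
              for (int j = ja; j < ja + 4; ++j)
                for (int i = ia; i < ia + 4; ++i)
                  phi(n, idx3(i, j, k, I, J)) = val;
          } else {
            const int ib = std::min(ia + 4, I), jb = std::min(ja + 4, J),
                      kb = std::min(ka + 4, K);
            const int li0 = si > 0 ? ia : ib - 1, lj0 = sj > 0 ? ja : jb - 1,
                      lk0 = sk > 0 ? ka : kb - 1;
            for (int kk = 0; kk < kb - ka; ++kk) {
              const int k = lk0 + sk * kk;
              for (int jj = 0; jj < jb - ja; ++jj) {
                const int j = lj0 + sj * jj;
                for (int ii = 0; ii < ib - ia; ++ii) {
                  const int i = li0 + si * ii;
                  const R_xlen_t v = idx3(i, j, k, I, J);
                  double num = Q(n, v);
                  const int ipr = i - si, jpr = j - sj, kpr = k - sk;
                  if (ax > 0 && ipr >= 0 && ipr < I)
                    num += ax * phi(n, idx3(ipr, j, k, I, J));
                  if (ay > 0 && jpr >= 0 && jpr < J)
                    num += ay * phi(n, idx3(i, jpr, k, I, J));
                  if (az > 0 && kpr >= 0 && kpr < K)
                    num += az * phi(n, idx3(i, j, kpr, I, J));
                  phi(n, v) = num / (ax + ay + az + sigma[v]);
                }
              }
            }
          }
        }
      }
    }
  }
  return phi;
}
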