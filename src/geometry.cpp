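#pragma GCC optimize("O3")
// Geometric machinery: interpolation, warping, composition, scaling-and-squaring
// integration of stationary velocity fields, and Jacobian determinants.
//
// Conventions (shared with the R layer):
//  * 2-D grids are n1 x n2 arrays, column-major, voxel index (i1, i2), i1 fastest.
//  * 3-D grids are n1 x n2 x n3.
//  * A deformation phi is stored as displacement-from-identity u in voxel units:
//      phi(x) = x + u(x); u is an (n1, n2[, n3], d) array, component c at
//      offset c * nvox.
//  * Out-of-bounds sampling clamps to the border voxel by default; zero padding
//    is available via `zero_pad`.

#include <RcppArmadillo.h>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif
using namespace Rcpp;

// Flush denormals to zero: gradients through deep squaring chains generate
// subnormal values that cripple throughput on x86 otherwise.
// [[Rcpp::export]]
void ca_fast_math_cpp() {
#ifdef __SSE2__
  _mm_setcsr(_mm_getcsr() | 0x8040);
#endif
}

// ---------------------------------------------------------------------------
// samplers

// Bilinear sample of C channels (channel stride cs) at continuous (p1, p2).
// Optionally returns d(value)/dp per channel (needed by backprop).
static inline void samp2(const double* f, int n1, int n2, int C, int cs,
                         double p1, double p2, bool zero_pad,
                         double* out, double* d1 = nullptr, double* d2 = nullptr) {
  if (!zero_pad) {
    bool cl1 = false, cl2 = false;
    if (p1 < 0)       { p1 = 0;       cl1 = true; }
    else if (p1 > n1 - 1) { p1 = n1 - 1; cl1 = true; }
    if (p2 < 0)       { p2 = 0;       cl2 = true; }
    else if (p2 > n2 - 1) { p2 = n2 - 1; cl2 = true; }
    int i0 = (int)std::floor(p1); if (i0 > n1 - 2) i0 = n1 - 2;
    int j0 = (int)std::floor(p2); if (j0 > n2 - 2) j0 = n2 - 2;
    double f1 = p1 - i0, f2 = p2 - j0;
    for (int c = 0; c < C; ++c) {
      const double* fc = f + (std::size_t)c * cs;
      double v00 = fc[i0     + n1 * j0],     v10 = fc[i0 + 1 + n1 * j0];
      double v01 = fc[i0     + n1 * (j0+1)], v11 = fc[i0 + 1 + n1 * (j0+1)];
      out[c] = (1 - f1) * (1 - f2) * v00 + f1 * (1 - f2) * v10 +
               (1 - f1) * f2 * v01 + f1 * f2 * v11;
      if (d1) d1[c] = cl1 ? 0.0 : (v10 - v00) * (1 - f2) + (v11 - v01) * f2;
      if (d2) d2[c] = cl2 ? 0.0 : (v01 - v00) * (1 - f1) + (v11 - v10) * f1;
    }
  } else {
    int i0 = (int)std::floor(p1), j0 = (int)std::floor(p2);
    double f1 = p1 - i0, f2 = p2 - j0;
    for (int c = 0; c < C; ++c) {
      const double* fc = f + (std::size_t)c * cs;
      auto at = [&](int i, int j) -> double {
        return (i < 0 || i >= n1 || j < 0 || j >= n2) ? 0.0 : fc[i + n1 * j];
      };
      double v00 = at(i0, j0), v10 = at(i0 + 1, j0);
      double v01 = at(i0, j0 + 1), v11 = at(i0 + 1, j0 + 1);
      out[c] = (1 - f1) * (1 - f2) * v00 + f1 * (1 - f2) * v10 +
               (1 - f1) * f2 * v01 + f1 * f2 * v11;
      if (d1) d1[c] = (v10 - v00) * (1 - f2) + (v11 - v01) * f2;
      if (d2) d2[c] = (v01 - v00) * (1 - f1) + (v11 - v10) * f1;
    }
  }
}

// Scatter-accumulate the adjoint of samp2 (clamp mode): adds the bilinear
// weights times g into gf for each channel.
static inline void samp2_acc(double* gf, int n1, int n2, int C, int cs,
                             double p1, double p2, const double* g) {
  if (p1 < 0) p1 = 0; else if (p1 > n1 - 1) p1 = n1 - 1;
  if (p2 < 0) p2 = 0; else if (p2 > n2 - 1) p2 = n2 - 1;
  int i0 = (int)std::floor(p1); if (i0 > n1 - 2) i0 = n1 - 2;
  int j0 = (int)std::floor(p2); if (j0 > n2 - 2) j0 = n2 - 2;
  double f1 = p1 - i0, f2 = p2 - j0;
  for (int c = 0; c < C; ++c) {
    double* fc = gf + (std::size_t)c * cs;
    fc[i0     + n1 * j0]       += (1 - f1) * (1 - f2) * g[c];
    fc[i0 + 1 + n1 * j0]       += f1 * (1 - f2) * g[c];
    fc[i0     + n1 * (j0 + 1)] += (1 - f1) * f2 * g[c];
    fc[i0 + 1 + n1 * (j0 + 1)] += f1 * f2 * g[c];
  }
}

// Trilinear sample, clamp or zero padding (no derivative needed in 3-D paths).
static inline void samp3(const double* f, int n1, int n2, int n3, int C, int cs,
                         double p1, double p2, double p3, bool zero_pad,
                         double* out) {
  if (!zero_pad) {
    if (p1 < 0) p1 = 0; else if (p1 > n1 - 1) p1 = n1 - 1;
    if (p2 < 0) p2 = 0; else if (p2 > n2 - 1) p2 = n2 - 1;
    if (p3 < 0) p3 = 0; else if (p3 > n3 - 1) p3 = n3 - 1;
    int i0 = (int)std::floor(p1); if (i0 > n1 - 2) i0 = n1 - 2;
    int j0 = (int)std::floor(p2); if (j0 > n2 - 2) j0 = n2 - 2;
    int k0 = (int)std::floor(p3); if (k0 > n3 - 2) k0 = n3 - 2;
    double f1 = p1 - i0, f2 = p2 - j0, f3 = p3 - k0;
    std::size_t s2 = (std::size_t)n1, s3 = (std::size_t)n1 * n2;
    for (int c = 0; c < C; ++c) {
      const double* fc = f + (std::size_t)c * cs;
      double acc = 0;
      for (int dk = 0; dk < 2; ++dk)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double w = (di ? f1 : 1 - f1) * (dj ? f2 : 1 - f2) * (dk ? f3 : 1 - f3);
            acc += w * fc[(i0 + di) + s2 * (j0 + dj) + s3 * (k0 + dk)];
          }
      out[c] = acc;
    }
  } else {
    int i0 = (int)std::floor(p1), j0 = (int)std::floor(p2), k0 = (int)std::floor(p3);
    double f1 = p1 - i0, f2 = p2 - j0, f3 = p3 - k0;
    std::size_t s2 = (std::size_t)n1, s3 = (std::size_t)n1 * n2;
    for (int c = 0; c < C; ++c) {
      const double* fc = f + (std::size_t)c * cs;
      double acc = 0;
      for (int dk = 0; dk < 2; ++dk)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            int i = i0 + di, j = j0 + dj, k = k0 + dk;
            if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3) continue;
            double w = (di ? f1 : 1 - f1) * (dj ? f2 : 1 - f2) * (dk ? f3 : 1 - f3);
            acc += w * fc[i + s2 * j + s3 * k];
          }
      out[c] = acc;
    }
  }
}

// ---------------------------------------------------------------------------
// warping

// Warp C channels through displacement u: out_c(x) = f_c(x + u(x)).
// dims: n1, n2 [, n3]; ndim 2 or 3; nearest=TRUE rounds the sample point
// (for label maps).
static void warp_nd(const double* f, const double* u, const int* n, int ndim,
                    int C, bool nearest, bool zero_pad, double* out) {
  if (ndim == 2) {
    int n1 = n[0], n2 = n[1];
    std::size_t nv = (std::size_t)n1 * n2;
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        std::size_t idx = i + (std::size_t)n1 * j;
        double p1 = i + u[idx], p2 = j + u[idx + nv];
        if (nearest) {
          int q1 = (int)std::lround(p1), q2 = (int)std::lround(p2);
          bool outp = (q1 < 0 || q1 >= n1 || q2 < 0 || q2 >= n2);
          if (outp && zero_pad) {
            for (int c = 0; c < C; ++c) out[idx + c * nv] = 0.0;
            continue;
          }
          q1 = std::min(std::max(q1, 0), n1 - 1);
          q2 = std::min(std::max(q2, 0), n2 - 1);
          for (int c = 0; c < C; ++c) out[idx + c * nv] = f[q1 + (std::size_t)n1 * q2 + c * nv];
        } else {
          double val[8];
          samp2(f, n1, n2, C, nv, p1, p2, zero_pad, val);
          for (int c = 0; c < C; ++c) out[idx + c * nv] = val[c];
        }
      }
  } else {
    int n1 = n[0], n2 = n[1], n3 = n[2];
    std::size_t nv = (std::size_t)n1 * n2 * n3, s2 = n1, s3 = (std::size_t)n1 * n2;
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          std::size_t idx = i + s2 * j + s3 * k;
          double p1 = i + u[idx], p2 = j + u[idx + nv], p3 = k + u[idx + 2 * nv];
          if (nearest) {
            int q1 = (int)std::lround(p1), q2 = (int)std::lround(p2), q3 = (int)std::lround(p3);
            bool outp = (q1 < 0 || q1 >= n1 || q2 < 0 || q2 >= n2 || q3 < 0 || q3 >= n3);
            if (outp && zero_pad) {
              for (int c = 0; c < C; ++c) out[idx + c * nv] = 0.0;
              continue;
            }
            q1 = std::min(std::max(q1, 0), n1 - 1);
            q2 = std::min(std::max(q2, 0), n2 - 1);
            q3 = std::min(std::max(q3, 0), n3 - 1);
            for (int c = 0; c < C; ++c) out[idx + c * nv] = f[q1 + s2 * q2 + s3 * q3 + c * nv];
          } else {
            double val[8];
            samp3(f, n1, n2, n3, C, nv, p1, p2, p3, zero_pad, val);
            for (int c = 0; c < C; ++c) out[idx + c * nv] = val[c];
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector ca_warp_cpp(NumericVector f, NumericVector u, IntegerVector dims,
                          int channels, bool nearest, bool zero_pad) {
  int ndim = dims.size();
  NumericVector out(f.size());
  warp_nd(f.begin(), u.begin(), dims.begin(), ndim, channels, nearest, zero_pad,
          out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// scaling-and-squaring integration

// One squaring: unew(x) = u(x) + u(x + u(x)), clamp-border sampling.
static void square_once_2d(const double* u, int n1, int n2, double* unew) {
  std::size_t nv = (std::size_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      std::size_t idx = i + (std::size_t)n1 * j;
      double p1 = i + u[idx], p2 = j + u[idx + nv];
      double val[2];
      samp2(u, n1, n2, 2, nv, p1, p2, false, val);
      unew[idx] = u[idx] + val[0];
      unew[idx + nv] = u[idx + nv] + val[1];
    }
}

static void square_once_3d(const double* u, int n1, int n2, int n3, double* unew) {
  std::size_t nv = (std::size_t)n1 * n2 * n3, s2 = n1, s3 = (std::size_t)n1 * n2;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        std::size_t idx = i + s2 * j + s3 * k;
        double val[3];
        samp3(u, n1, n2, n3, 3, nv, i + u[idx], j + u[idx + nv], k + u[idx + 2 * nv],
              false, val);
        unew[idx] = u[idx] + val[0];
        unew[idx + nv] = u[idx + nv] + val[1];
        unew[idx + 2 * nv] = u[idx + 2 * nv] + val[2];
      }
}

// [[Rcpp::export]]
NumericVector ca_integrate_cpp(NumericVector v, IntegerVector dims, int steps) {
  int ndim = dims.size();
  std::size_t nfield = v.size();
  NumericVector u(nfield), tmp(nfield);
  double scale = std::ldexp(1.0, -steps); // 1 / 2^steps
  for (std::size_t i = 0; i < nfield; ++i) u[i] = v[i] * scale;
  for (int s = 0; s < steps; ++s) {
    if (ndim == 2) square_once_2d(u.begin(), dims[0], dims[1], tmp.begin());
    else           square_once_3d(u.begin(), dims[0], dims[1], dims[2], tmp.begin());
    std::swap(u, tmp);
  }
  return u;
}

// ---------------------------------------------------------------------------
// training-side 2-D integration with tape + backward (used by the model)

void integrate2_tape(const arma::vec& v, int n1, int n2, int steps,
                     std::vector<arma::vec>& tape) {
  tape.clear();
  tape.reserve(steps + 1);
  arma::vec u = v * std::ldexp(1.0, -steps);
  tape.push_back(u);
  arma::vec tmp(u.n_elem);
  for (int s = 0; s < steps; ++s) {
    square_once_2d(tape.back().memptr(), n1, n2, tmp.memptr());
    tape.push_back(tmp);
  }
}

// Adjoint of one squaring. g: grad wrt unew -> returns grad wrt u.
static void square_once_2d_bwd(const double* u, int n1, int n2,
                               const double* g, double* gu) {
  std::size_t nv = (std::size_t)n1 * n2;
  for (std::size_t i = 0; i < 2 * nv; ++i) gu[i] = g[i]; // identity term
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      std::size_t idx = i + (std::size_t)n1 * j;
      double p1 = i + u[idx], p2 = j + u[idx + nv];
      double val[2], d1[2], d2[2];
      samp2(u, n1, n2, 2, nv, p1, p2, false, val, d1, d2);
      const double gout[2] = { g[idx], g[idx + nv] };
      // field slot: scatter bilinear weights
      samp2_acc(gu, n1, n2, 2, nv, p1, p2, gout);
      // displacement slot: through the sample position
      gu[idx]      += gout[0] * d1[0] + gout[1] * d1[1];
      gu[idx + nv] += gout[0] * d2[0] + gout[1] * d2[1];
    }
}

arma::vec integrate2_bwd(const std::vector<arma::vec>& tape, int n1, int n2,
                         const arma::vec& g_final) {
  int steps = (int)tape.size() - 1;
  arma::vec g = g_final, gu(g_final.n_elem);
  for (int s = steps - 1; s >= 0; --s) {
    square_once_2d_bwd(tape[s].memptr(), n1, n2, g.memptr(), gu.memptr());
    g = gu;
  }
  return g * std::ldexp(1.0, -steps);
}

// Warp single-channel image, with backward. Used by the model and registration.
void warp2_img(const double* f, const double* u, int n1, int n2, double* out) {
  int dims[2] = { n1, n2 };
  warp_nd(f, u, dims, 2, 1, false, false, out);
}

// Returns grads wrt image (accumulated into gimg if not null) and displacement.
void warp2_img_bwd(const double* f, const double* u, int n1, int n2,
                   const double* gout, double* gimg, double* gu) {
  std::size_t nv = (std::size_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      std::size_t idx = i + (std::size_t)n1 * j;
      double p1 = i + u[idx], p2 = j + u[idx + nv];
      double val, d1, d2;
      samp2(f, n1, n2, 1, nv, p1, p2, false, &val, &d1, &d2);
      double g = gout[idx];
      if (gimg) samp2_acc(gimg, n1, n2, 1, nv, p1, p2, &g);
      gu[idx]      += g * d1;
      gu[idx + nv] += g * d2;
    }
}

// ---------------------------------------------------------------------------
// Jacobian determinant

// d/dx_d of component data at voxel, central differences interior, one-sided
// at borders (spacing 1 voxel).
static inline double diff1(const double* f, int i, int n, std::size_t stride,
                           std::size_t idx) {
  if (i > 0 && i < n - 1) return 0.5 * (f[idx + stride] - f[idx - stride]);
  if (i == 0) return f[idx + stride] - f[idx];
  return f[idx] - f[idx - stride];
}

// [[Rcpp::export]]
NumericVector ca_jacdet_cpp(NumericVector u, IntegerVector dims) {
  int ndim = dims.size();
  if (ndim == 2) {
    int n1 = dims[0], n2 = dims[1];
    std::size_t nv = (std::size_t)n1 * n2;
    NumericVector out(nv);
    const double* u1 = u.begin();
    const double* u2 = u.begin() + nv;
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        std::size_t idx = i + (std::size_t)n1 * j;
        double a11 = 1.0 + diff1(u1, i, n1, 1, idx);
        double a12 = diff1(u1, j, n2, n1, idx);
        double a21 = diff1(u2, i, n1, 1, idx);
        double a22 = 1.0 + diff1(u2, j, n2, n1, idx);
        out[idx] = a11 * a22 - a12 * a21;
      }
    return out;
  }
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::size_t nv = (std::size_t)n1 * n2 * n3, s2 = n1, s3 = (std::size_t)n1 * n2;
  NumericVector out(nv);
  const double* uc[3] = { u.begin(), u.begin() + nv, u.begin() + 2 * nv };
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        std::size_t idx = i + s2 * j + s3 * k;
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          J[c][0] = diff1(uc[c], i, n1, 1, idx);
          J[c][1] = diff1(uc[c], j, n2, s2, idx);
          J[c][2] = diff1(uc[c], k, n3, s3, idx);
          J[c][c] += 1.0;
        }
        out[idx] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
                 - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
                 + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// ---------------------------------------------------------------------------
// bending energy and displacement magnitude (2-D and 3-D), with 2-D gradients

// Mean over interior voxels of sum over components of squared Laplacian.
double bending2(const double* u, int n1, int n2) {
  std::size_t nv = (std::size_t)n1 * n2;
  double acc = 0;
  for (int c = 0; c < 2; ++c) {
    const double* f = u + c * nv;
    for (int j = 1; j < n2 - 1; ++j)
      for (int i = 1; i < n1 - 1; ++i) {
        std::size_t idx = i + (std::size_t)n1 * j;
        double lap = f[idx - 1] + f[idx + 1] + f[idx - n1] + f[idx + n1] - 4.0 * f[idx];
        acc += lap * lap;
      }
  }
  return acc / ((double)(n1 - 2) * (n2 - 2));
}

// Adds d(bending2)/du to gu.
void bending2_grad(const double* u, int n1, int n2, double w, double* gu) {
  std::size_t nv = (std::size_t)n1 * n2;
  double norm = 2.0 * w / ((double)(n1 - 2) * (n2 - 2));
  std::vector<double> lap(nv);
  for (int c = 0; c < 2; ++c) {
    const double* f = u + c * nv;
    std::fill(lap.begin(), lap.end(), 0.0);
    for (int j = 1; j < n2 - 1; ++j)
      for (int i = 1; i < n1 - 1; ++i) {
        std::size_t idx = i + (std::size_t)n1 * j;
        lap[idx] = f[idx - 1] + f[idx + 1] + f[idx - n1] + f[idx + n1] - 4.0 * f[idx];
      }
    double* g = gu + c * nv;
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        std::size_t idx = i + (std::size_t)n1 * j;
        double a = -4.0 * lap[idx];
        if (i > 0)      a += lap[idx - 1];
        if (i < n1 - 1) a += lap[idx + 1];
        if (j > 0)      a += lap[idx - n1];
        if (j < n2 - 1) a += lap[idx + n1];
        g[idx] += norm * a;
      }
  }
}

// [[Rcpp::export]]
double ca_bending_cpp(NumericVector u, IntegerVector dims) {
  int ndim = dims.size();
  if (ndim == 2) return bending2(u.begin(), dims[0], dims[1]);
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::size_t nv = (std::size_t)n1 * n2 * n3, s2 = n1, s3 = (std::size_t)n1 * n2;
  double acc = 0;
  for (int c = 0; c < 3; ++c) {
    const double* f = u.begin() + c * nv;
    for (int k = 1; k < n3 - 1; ++k)
      for (int j = 1; j < n2 - 1; ++j)
        for (int i = 1; i < n1 - 1; ++i) {
          std::size_t idx = i + s2 * j + s3 * k;
          double lap = f[idx - 1] + f[idx + 1] + f[idx - s2] + f[idx + s2] +
                       f[idx - s3] + f[idx + s3] - 6.0 * f[idx];
          acc += lap * lap;
        }
  }
  return acc / ((double)(n1 - 2) * (n2 - 2) * (n3 - 2));
}
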