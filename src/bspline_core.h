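#ifndef GRIDFF_BSPLINE_CORE_H
#define GRIDFF_BSPLINE_CORE_H

#include "gridff_common.h"

namespace gridff {

// uniform cubic B-spline basis on the 4-node stencil for fractional t in [0,1]
inline void bspline_w(double t, double* w, double* dw) {
  double u = 1.0 - t;
  w[0] = u * u * u / 6.0;
  w[1] = (3.0 * t * t * t - 6.0 * t * t + 4.0) / 6.0;
  w[2] = (-3.0 * t * t * t + 3.0 * t * t + 3.0 * t + 1.0) / 6.0;
  w[3] = t * t * t / 6.0;
  dw[0] = -u * u / 2.0;
  dw[1] = (9.0 * t * t - 12.0 * t) / 6.0;
  dw[2] = (-9.0 * t * t + 6.0 * t + 3.0) / 6.0;
  dw[3] = t * t / 2.0;
}

inline int wrap_index(int i, int n, bool periodic) {
  if (periodic) { i %= n; if (i < 0) i += n; return i; }
  if (i < 0) return 0;          // clamped: repeated edge coefficient
  if (i > n - 1) return n - 1;
  return i;
}

// Tricubic tensor-product evaluation of ncomp coefficient arrays sharing one
// grid, at grid-fractional coordinates u (already folded on periodic axes).
// Values and gradients are in grid-fractional units; the caller applies the
// inverse-step transform.  Evaluation order: z innermost (contiguous), then
// y, then x.
inline void tricubic_eval(const double* const* coeff, int ncomp, int nx,
                          int ny, int nz, bool px, bool py, bool pz,
                          double ux, double uy, double uz, double* val,
                          double (*grad)[3]) {
  int ix = (int)std::floor(ux), iy = (int)std::floor(uy),
      iz = (int)std::floor(uz);
  // keep t in [0,1] at the very top of clamped axes
  if (!px && ix > nx - 2) ix = nx - 2;
  if (!py && iy > ny - 2) iy = ny - 2;
  if (!pz && iz > nz - 2) iz = nz - 2;
  double tx = ux - ix, ty = uy - iy, tz = uz - iz;
  double wx[4], dwx[4], wy[4], dwy[4], wz[4], dwz[4];
  bspline_w(tx, wx, dwx);
  bspline_w(ty, wy, dwy);
  bspline_w(tz, wz, dwz);
  int jx[4], jy[4], jz[4];
  for (int m = 0; m < 4; ++m) {
    jx[m] = wrap_index(ix - 1 + m, nx, px);
    jy[m] = wrap_index(iy - 1 + m, ny, py);
    jz[m] = wrap_index(iz - 1 + m, nz, pz);
  }
  for (int c = 0; c < ncomp; ++c) {
    const double* C = coeff[c];
    double v = 0, gx = 0, gy = 0, gz = 0;
    for (int a = 0; a < 4; ++a) {
      double vy = 0, gyy = 0, gzy = 0;
      for (int b = 0; b < 4; ++b) {
        const double* line = C + ((R_xlen_t)jx[a] * ny + jy[b]) * nz;
        double vz = 0, gzz = 0;
        for (int m = 0; m < 4; ++m) {
          double cv = line[jz[m]];
          vz += wz[m] * cv;
          gzz += dwz[m] * cv;
        }
        vy += wy[b] * vz;
        gyy += dwy[b] * vz;
        gzy += wy[b] * gzz;
      }
      v += wx[a] * vy;
      gx += dwx[a] * vy;
      gy += wx[a] * gyy;
      gz += wx[a] * gzy;
    }
    val[c] = v;
    if (grad) { grad[c][0] = gx; grad[c][1] = gy; grad[c][2] = gz; }
  }
}

}  // namespace gridff

#endif
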