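#include "gridff_common.h"
using namespace Rcpp;
using gridff::Vec3;
using gridff::K_E;

// Structure factors S(k) = sum_j q_j exp(-i k.r_j) for a rigid charge set.
// [[Rcpp::export]]
List cpp_structure_factors(NumericMatrix kvec, NumericMatrix pos,
                           NumericVector q) {
  int m = kvec.nrow(), n = pos.nrow();
  NumericVector sre(m), sim(m);
  for (int k = 0; k < m; ++k) {
    double kx = kvec(k, 0), ky = kvec(k, 1), kz = kvec(k, 2);
    double re = 0, im = 0;
    for (int j = 0; j < n; ++j) {
      double ph = kx * pos(j, 0) + ky * pos(j, 1) + kz * pos(j, 2);
      re += q[j] * std::cos(ph);
      im -= q[j] * std::sin(ph);
    }
    sre[k] = re; sim[k] = im;
  }
  return List::create(_["re"] = sre, _["im"] = sim);
}

// Converged real + reciprocal Ewald potential (and field) of a rigid periodic
// charge set, evaluated at arbitrary points.  The reciprocal part uses
// precomputed structure factors and per-k coefficients
// coef_k = 2 * (4 pi K_E / V) * exp(-k^2/(4 beta^2)) / k^2 over a half-space
// enumeration; the real part sums erfc over an explicit image-expanded atom
// list truncated at r_cut.  Points are folded into the lateral cell by the
// caller.  Tin-foil boundary (k = 0 dropped); the cell must be neutral.
// [[Rcpp::export]]
List cpp_ewald_eval(NumericMatrix points, NumericMatrix kvec,
                    NumericVector coef, NumericVector sre, NumericVector sim,
                    NumericMatrix spos, NumericVector q, double beta,
                    double r_cut, bool grad) {
  int np = points.nrow(), nk = kvec.nrow(), na = spos.nrow();
  NumericVector V(np);
  NumericMatrix G(grad ? np : 1, 3);
  double rc2 = r_cut * r_cut;
  double c2 = 2.0 * beta / std::sqrt(M_PI);
  for (int p = 0; p < np; ++p) {
    Vec3 r(points(p, 0), points(p, 1), points(p, 2));
    double v = 0, gx = 0, gy = 0, gz = 0;
    for (int j = 0; j < na; ++j) {
      Vec3 d(r.x - spos(j, 0), r.y - spos(j, 1), r.z - spos(j, 2));
      double d2 = d.norm2();
      if (d2 > rc2) continue;
      double rr = std::sqrt(d2);
      if (rr < 1e-6) stop("ewald: evaluation point coincides with an atom");
      double er = std::erfc(beta * rr);
      v += K_E * q[j] * er / rr;
      if (grad) {
        // dV/dr = K_E q (-erfc(br)/r^2 - 2b/sqrt(pi) exp(-b^2 r^2)/r)
        double dv = K_E * q[j] *
          (-er / d2 - c2 * std::exp(-beta * beta * d2) / rr);
        double s = dv / rr;
        gx += s * d.x; gy += s * d.y; gz += s * d.z;
      }
    }
    for (int k = 0; k < nk; ++k) {
      double kx = kvec(k, 0), ky = kvec(k, 1), kz = kvec(k, 2);
      double ph = kx * r.x + ky * r.y + kz * r.z;
      double cph = std::cos(ph), sph = std::sin(ph);
      double re = sre[k] * cph - sim[k] * sph;   // Re[S exp(i k.r)]
      v += coef[k] * re;
      if (grad) {
        double im = sre[k] * sph + sim[k] * cph; // Im[S exp(i k.r)]
        gx -= coef[k] * im * kx;
        gy -= coef[k] * im * ky;
        gz -= coef[k] * im * kz;
      }
    }
    V[p] = v;
    if (grad) { G(p, 0) = gx; G(p, 1) = gy; G(p, 2) = gz; }
  }
  return List::create(_["V"] = V, _["G"] = G);
}
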