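#include "gridff_common.h"
using namespace Rcpp;
using gridff::Vec3;

// Morse pair law E = eps*(exp(-2 a d) - 2 exp(-a d)), d = r - R, with
// analytic radial derivative.  Vectorized over r for testing convenience.
// [[Rcpp::export]]
List cpp_morse_pair(NumericVector r, double eps, double Rij, double alpha) {
  int n = r.size();
  NumericVector E(n), dE(n);
  for (int i = 0; i < n; ++i) {
    if (!(r[i] > 0)) stop("morse_pair: r must be > 0");
    double eL = std::exp(-alpha * (r[i] - Rij));
    double eP = eL * eL;
    E[i] = eps * (eP - 2.0 * eL);
    dE[i] = eps * alpha * (-2.0 * eP + 2.0 * eL);
  }
  return List::create(_["E"] = E, _["dE_dr"] = dE);
}

// Direct Morse sum of molecule atoms against an explicit (image-expanded)
// substrate atom list, truncated at r_cut.  Returns energy and forces on the
// molecule atoms (exact gradients of the truncated sum).
// [[Rcpp::export]]
List cpp_direct_morse(NumericMatrix pos, NumericVector eps_i, NumericVector R_i,
                      NumericMatrix spos, NumericVector eps_j, NumericVector R_j,
                      double alpha, double r_cut) {
  int n = pos.nrow(), m = spos.nrow();
  double E = 0.0;
  NumericMatrix F(n, 3);
  double rc2 = r_cut * r_cut;
  for (int i = 0; i < n; ++i) {
    double se_i = std::sqrt(eps_i[i]);
    Vec3 pi(pos(i, 0), pos(i, 1), pos(i, 2));
    double fx = 0, fy = 0, fz = 0;
    for (int j = 0; j < m; ++j) {
      Vec3 d(pi.x - spos(j, 0), pi.y - spos(j, 1), pi.z - spos(j, 2));
      double r2 = d.norm2();
      if (r2 > rc2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-6) stop("direct sum: overlapping atoms (r < 1e-6 Angstrom)");
      double eij = se_i * std::sqrt(eps_j[j]);
      double Rij = R_i[i] + R_j[j];
      double eL = std::exp(-alpha * (r - Rij));
      double eP = eL * eL;
      E += eij * (eP - 2.0 * eL);
      double dEdr = eij * alpha * (-2.0 * eP + 2.0 * eL);
      double s = -dEdr / r;  // F = -dE/dr * rhat
      fx += s * d.x; fy += s * d.y; fz += s * d.z;
    }
    F(i, 0) = fx; F(i, 1) = fy; F(i, 2) = fz;
  }
  return List::create(_["E"] = E, _["F"] = F);
}

// Plain image-summed Coulomb (no Ewald): molecule charges against the
// explicit image-expanded substrate list.  No cutoff: the image count is the
// stated truncation.
// [[Rcpp::export]]
List cpp_direct_coulomb(NumericMatrix pos, NumericVector q_i,
                        NumericMatrix spos, NumericVector q_j) {
  int n = pos.nrow(), m = spos.nrow();
  double E = 0.0;
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 pi(pos(i, 0), pos(i, 1), pos(i, 2));
    double fx = 0, fy = 0, fz = 0;
    for (int j = 0; j < m; ++j) {
      Vec3 d(pi.x - spos(j, 0), pi.y - spos(j, 1), pi.z - spos(j, 2));
      double r = d.norm();
      if (r < 1e-6) stop("direct sum: overlapping atoms (r < 1e-6 Angstrom)");
      double pref = gridff::K_E * q_i[i] * q_j[j];
      E += pref / r;
      double s = pref / (r * r * r);  // -d(1/r)/dr * rhat = rvec/r^3
      fx += s * d.x; fy += s * d.y; fz += s * d.z;
    }
    F(i, 0) = fx; F(i, 1) = fy; F(i, 2) = fz;
  }
  return List::create(_["E"] = E, _["F"] = F);
}

// Factorized Morse evaluation (grid-free): for probe atoms with weights
// wP = sqrt(eps_i) e^{2 a R_i}, wL = sqrt(eps_i) e^{a R_i} against inner sums
// over the substrate; used to check the factorization identity against the
// direct pair law without any grids involved.
// [[Rcpp::export]]
NumericVector cpp_factorized_morse(NumericMatrix pos, NumericVector eps_i,
                                   NumericVector R_i, NumericMatrix spos,
                                   NumericVector eps_j, NumericVector R_j,
                                   double alpha) {
  int n = pos.nrow(), m = spos.nrow();
  NumericVector E(n);
  for (int i = 0; i < n; ++i) {
    double GP = 0.0, GL = 0.0;
    Vec3 pi(pos(i, 0), pos(i, 1), pos(i, 2));
    for (int j = 0; j < m; ++j) {
      Vec3 d(pi.x - spos(j, 0), pi.y - spos(j, 1), pi.z - spos(j, 2));
      double r = d.norm();
      double eL = std::sqrt(eps_j[j]) * std::exp(-alpha * (r - R_j[j]));
      GL += eL;
      GP += std::sqrt(eps_j[j]) * std::exp(-2.0 * alpha * (r - R_j[j]));
    }
    double se = std::sqrt(eps_i[i]);
    E[i] = se * std::exp(2.0 * alpha * R_i[i]) * GP -
           2.0 * se * std::exp(alpha * R_i[i]) * GL;
  }
  return E;
}

// counter-based normal deviates; deterministic in (seed, stream, counter)
// [[Rcpp::export]]
NumericVector cpp_rng_normals(double seed, double stream, double counter, int n) {
  NumericVector out(n);
  std::uint64_t s = (std::uint64_t)seed, st = (std::uint64_t)stream,
                c = (std::uint64_t)counter;
  for (int i = 0; i < n; ++i) out[i] = gridff::hash_normal(s, st, c, i);
  return out;
}
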