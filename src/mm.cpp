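#include "bspline_core.h"
using namespace Rcpp;
using gridff::Vec3;
using gridff::K_E;

List cpp_direct_morse(NumericMatrix, NumericVector, NumericVector,
                      NumericMatrix, NumericVector, NumericVector, double,
                      double);
List cpp_ewald_eval(NumericMatrix, NumericMatrix, NumericVector,
                    NumericVector, NumericVector, NumericMatrix,
                    NumericVector, double, double, bool);

// Minimal valence force field: harmonic bonds E = k/2 (r-r0)^2, harmonic
// angles E = k/2 (th-th0)^2, 3-term cosine torsions
// E = sum_m k_m (1 + cos(m phi - gamma_m)), plus intramolecular nonbonded
// Morse + Coulomb over the supplied (non-excluded) pair list.  No periodic
// images of the molecule.
// [[Rcpp::export]]
List cpp_intramol(NumericMatrix pos, IntegerMatrix bonds, NumericVector bk,
                  NumericVector br0, IntegerMatrix angles, NumericVector ak,
                  NumericVector ath0, IntegerMatrix torsions,
                  NumericMatrix tk, NumericMatrix tg, IntegerMatrix nbpairs,
                  NumericVector eps, NumericVector R, NumericVector q,
                  double alpha, double r_cut) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  double Eb = 0.0, Enb = 0.0;
  auto P = [&](int i) { return Vec3(pos(i, 0), pos(i, 1), pos(i, 2)); };
  auto addF = [&](int i, const Vec3& f) {
    F(i, 0) += f.x; F(i, 1) += f.y; F(i, 2) += f.z;
  };
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    Vec3 d = P(i) - P(j);
    double r = d.norm();
    if (r < 1e-8) stop("intramolecular: zero bond length");
    double dr = r - br0[b];
    Eb += 0.5 * bk[b] * dr * dr;
    Vec3 f = d * (-bk[b] * dr / r);
    addF(i, f);
    addF(j, f * -1.0);
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);  // j = apex
    Vec3 u = P(i) - P(j), v = P(k) - P(j);
    double nu = u.norm(), nv = v.norm();
    double ct = u.dot(v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-16));
    double th = std::acos(ct);
    double dEdth = ak[a] * (th - ath0[a]);
    Eb += 0.5 * ak[a] * (th - ath0[a]) * (th - ath0[a]);
    Vec3 uh = u * (1.0 / nu), vh = v * (1.0 / nv);
    Vec3 dthi = (vh - uh * ct) * (-1.0 / (st * nu));
    Vec3 dthk = (uh - vh * ct) * (-1.0 / (st * nv));
    addF(i, dthi * -dEdth);
    addF(k, dthk * -dEdth);
    addF(j, (dthi + dthk) * dEdth);
  }
  for (int t = 0; t < torsions.nrow(); ++t) {
    int i0 = torsions(t, 0), i1 = torsions(t, 1), i2 = torsions(t, 2),
        i3 = torsions(t, 3);
    Vec3 b1 = P(i1) - P(i0), b2 = P(i2) - P(i1), b3 = P(i3) - P(i2);
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    double n1n = n1.norm2(), n2n = n2.norm2(), lb2 = b2.norm();
    if (n1n < 1e-12 || n2n < 1e-12 || lb2 < 1e-8) continue;  // collinear
    double x = n1.dot(n2);
    double y = n1.cross(n2).dot(b2) * (1.0 / lb2);
    double phi = std::atan2(y, x);
    double dEdphi = 0.0;
    for (int m = 0; m < 3; ++m) {
      double km = tk(t, m);
      if (km == 0) continue;
      double arg = (m + 1) * phi - tg(t, m);
      Eb += km * (1.0 + std::cos(arg));
      dEdphi -= km * (m + 1) * std::sin(arg);
    }
    Vec3 dp0 = n1 * (-lb2 / n1n);
    Vec3 dp3 = n2 * (lb2 / n2n);
    double c12 = b1.dot(b2) / (lb2 * lb2), c32 = b3.dot(b2) / (lb2 * lb2);
    Vec3 dp1 = dp0 * (-1.0 - c12) + dp3 * c32;
    Vec3 dp2 = dp0 * c12 - dp3 * (1.0 + c32);
    addF(i0, dp0 * -dEdphi);
    addF(i1, dp1 * -dEdphi);
    addF(i2, dp2 * -dEdphi);
    addF(i3, dp3 * -dEdphi);
  }
  double rc2 = r_cut * r_cut;
  for (int p = 0; p < nbpairs.nrow(); ++p) {
    int i = nbpairs(p, 0), j = nbpairs(p, 1);
    Vec3 d = P(i) - P(j);
    double r2 = d.norm2();
    double r = std::sqrt(r2);
    if (r < 1e-6) stop("intramolecular: overlapping nonbonded pair");
    double dEdr = 0.0, e = 0.0;
    if (r2 <= rc2) {
      double eij = std::sqrt(eps[i] * eps[j]);
      double Rij = R[i] + R[j];
      double eL = std::exp(-alpha * (r - Rij));
      e += eij * (eL * eL - 2.0 * eL);
      dEdr += eij * alpha * (-2.0 * eL * eL + 2.0 * eL);
    }
    double pref = K_E * q[i] * q[j];
    e += pref / r;
    dEdr -= pref / r2;
    Enb += e;
    Vec3 f = d * (-dEdr / r);
    addF(i, f);
    addF(j, f * -1.0);
  }
  return List::create(_["E_bonded"] = Eb, _["E_intra_nb"] = Enb, _["F"] = F);
}

// Surface terms through the fitted tricubic field.  Components: Pauli and
// London Morse factors and the Coulomb potential.  Atoms above the grid top
// contribute zero (asymptotic region); atoms below the grid bottom are a
// domain error.
// [[Rcpp::export]]
List cpp_surf_grid(NumericMatrix pos, NumericVector wP, NumericVector wL,
                   NumericVector q, List coeffs, IntegerVector dims,
                   NumericVector origin, NumericMatrix sinv,
                   LogicalVector periodic) {
  int n = pos.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector cvP = coeffs[0], cvL = coeffs[1], cvC = coeffs[2];
  const double* cptr[3] = {cvP.begin(), cvL.begin(), cvC.begin()};
  NumericMatrix F(n, 3);
  NumericVector Em(n), Ec(n);
  double nmax[3] = {(double)nx, (double)ny, (double)nz};
  for (int i = 0; i < n; ++i) {
    double rx = pos(i, 0) - origin[0], ry = pos(i, 1) - origin[1],
           rz = pos(i, 2) - origin[2];
    double u[3];
    for (int d = 0; d < 3; ++d)
      u[d] = sinv(d, 0) * rx + sinv(d, 1) * ry + sinv(d, 2) * rz;
    for (int d = 0; d < 3; ++d) {
      if (periodic[d]) {
        u[d] -= nmax[d] * std::floor(u[d] / nmax[d]);
        if (u[d] >= nmax[d]) u[d] = 0.0;
      }
    }
    if (u[2] > nmax[2] - 1) continue;  // above the grid: asymptotic zero
    if (u[2] < -1e-9)
      stop("surface field: atom below the grid bottom (z domain error)");
    if (u[2] < 0) u[2] = 0;
    double val[3];
    double g[3][3];
    gridff::tricubic_eval(cptr, 3, nx, ny, nz, periodic[0], periodic[1],
                          periodic[2], u[0], u[1], u[2], val, g);
    Em[i] = wP[i] * val[0] - 2.0 * wL[i] * val[1];
    Ec[i] = q[i] * val[2];
    for (int d = 0; d < 3; ++d) {
      // chain rule d/dr = sinv^T d/du, then F = -dE/dr
      double gP = sinv(0, d) * g[0][0] + sinv(1, d) * g[0][1] +
                  sinv(2, d) * g[0][2];
      double gL = sinv(0, d) * g[1][0] + sinv(1, d) * g[1][1] +
                  sinv(2, d) * g[1][2];
      double gC = sinv(0, d) * g[2][0] + sinv(1, d) * g[2][1] +
                  sinv(2, d) * g[2][2];
      F(i, d) = -(wP[i] * gP - 2.0 * wL[i] * gL + q[i] * gC);
    }
  }
  return List::create(_["E_morse"] = Em, _["E_coul"] = Ec, _["F"] = F);
}

// Surface terms by direct sums: Morse against the image-expanded substrate
// list (cutoff r_cut) and Coulomb via the converged Ewald tables.  Molecule
// positions are folded into the lateral cell first (tmat maps fractional ->
// Cartesian, tinv the inverse; fold on axes 1 and 2 only).
// [[Rcpp::export]]
List cpp_surf_direct(NumericMatrix pos, NumericVector eps_i, NumericVector R_i,
                     NumericVector q_i, NumericMatrix spos, NumericVector eps_j,
                     NumericVector R_j, double alpha, double r_cut,
                     NumericMatrix kvec, NumericVector coef, NumericVector sre,
                     NumericVector sim, NumericMatrix repos, NumericVector req,
                     double beta, double r_cut_real, NumericMatrix tmat,
                     NumericMatrix tinv) {
  int n = pos.nrow();
  NumericMatrix folded(n, 3);
  for (int i = 0; i < n; ++i) {
    double u[3];
    for (int d = 0; d < 3; ++d)
      u[d] = tinv(d, 0) * pos(i, 0) + tinv(d, 1) * pos(i, 1) +
             tinv(d, 2) * pos(i, 2);
    u[0] -= std::floor(u[0]);
    u[1] -= std::floor(u[1]);
    for (int d = 0; d < 3; ++d)
      folded(i, d) = tmat(d, 0) * u[0] + tmat(d, 1) * u[1] +
                     tmat(d, 2) * u[2];
  }
  List morse = cpp_direct_morse(folded, eps_i, R_i, spos, eps_j, R_j, alpha,
                                r_cut);
  List ew = cpp_ewald_eval(folded, kvec, coef, sre, sim, repos, req, beta,
                           r_cut_real, true);
  NumericMatrix Fm = morse["F"];
  NumericVector V = ew["V"];
  NumericMatrix G = ew["G"];
  NumericMatrix F(n, 3);
  double Ec = 0.0;
  for (int i = 0; i < n; ++i) {
    Ec += q_i[i] * V[i];
    for (int d = 0; d < 3; ++d) F(i, d) = Fm(i, d) - q_i[i] * G(i, d);
  }
  return List::create(_["E_morse"] = morse["E"], _["E_coul"] = Ec,
                      _["F"] = F);
}
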