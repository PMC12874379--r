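#include "gridff_common.h"
using namespace Rcpp;
using gridff::Vec3;
using gridff::grid_index;

// Project the factorized Morse inner sums onto grid nodes:
//   G_P(r) = sum_j sqrt(eps_j) exp(-2 a (|r - r_j| - R_j))
//   G_L(r) = sum_j sqrt(eps_j) exp(-  a (|r - r_j| - R_j))
// over an explicit (image-expanded) substrate atom list, truncated at r_cut.
// Node positions: origin + ix*da + iy*db + iz*dc; z-fastest storage.
// [[Rcpp::export]]
List cpp_project_morse(NumericMatrix spos, NumericVector eps_j,
                       NumericVector R_j, NumericVector origin,
                       NumericMatrix step, IntegerVector dims, double alpha,
                       double r_cut) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = spos.nrow();
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector GP(ntot), GL(ntot);
  Vec3 da(step(0, 0), step(1, 0), step(2, 0));
  Vec3 db(step(0, 1), step(1, 1), step(2, 1));
  Vec3 dc(step(0, 2), step(1, 2), step(2, 2));
  Vec3 o(origin[0], origin[1], origin[2]);
  double rc2 = r_cut * r_cut;
  std::vector<double> se(m), px(m), py(m), pz(m), Rj(m);
  for (int j = 0; j < m; ++j) {
    se[j] = std::sqrt(eps_j[j]);
    px[j] = spos(j, 0); py[j] = spos(j, 1); pz[j] = spos(j, 2);
    Rj[j] = R_j[j];
  }
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      Vec3 base = o + da * ix + db * iy;
      for (int iz = 0; iz < nz; ++iz) {
        Vec3 r = base + dc * iz;
        double gp = 0, gl = 0;
        for (int j = 0; j < m; ++j) {
          double dx = r.x - px[j], dy = r.y - py[j], dz = r.z - pz[j];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > rc2) continue;
          double d = std::sqrt(d2);
          if (d < 1e-3)
            stop("grid node within 1e-3 Angstrom of a substrate atom; "
                 "choose a different grid window");
          double eL = se[j] * std::exp(-alpha * (d - Rj[j]));
          gl += eL;
          gp += eL * eL / se[j];
        }
        R_xlen_t id = grid_index(ix, iy, iz, ny, nz);
        GP[id] = gp; GL[id] = gl;
      }
    }
  }
  return List::create(_["pauli"] = GP, _["london"] = GL);
}

// Spread point charges onto a fully periodic grid as a Gaussian charge
// density (width sigma, truncated at trunc*sigma, renormalized so each atom
// deposits exactly q_j).  Output units: e / Angstrom^3.
// [[Rcpp::export]]
NumericVector cpp_assign_gaussian(NumericMatrix pos, NumericVector q,
                                  NumericVector origin, NumericMatrix step,
                                  IntegerVector dims, double sigma,
                                  double trunc) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pos.nrow();
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector rho(ntot);
  // assume orthogonal-axis steps for the Poisson grid (validated in R)
  double hx = step(0, 0), hy = step(1, 1), hz = step(2, 2);
  double vox = hx * hy * hz;
  double rad = trunc * sigma;
  int wx = (int)std::ceil(rad / hx), wy = (int)std::ceil(rad / hy),
      wz = (int)std::ceil(rad / hz);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> weights;
  std::vector<R_xlen_t> idx;
  for (int a = 0; a < n; ++a) {
    double ux = (pos(a, 0) - origin[0]) / hx;
    double uy = (pos(a, 1) - origin[1]) / hy;
    double uz = (pos(a, 2) - origin[2]) / hz;
    int cx = (int)std::floor(ux), cy = (int)std::floor(uy),
        cz = (int)std::floor(uz);
    weights.clear(); idx.clear();
    double wsum = 0;
    for (int ix = cx - wx; ix <= cx + wx + 1; ++ix) {
      double dx = (ix - ux) * hx;
      int jx = ((ix % nx) + nx) % nx;
      for (int iy = cy - wy; iy <= cy + wy + 1; ++iy) {
        double dy = (iy - uy) * hy;
        int jy = ((iy % ny) + ny) % ny;
        double d2xy = dx * dx + dy * dy;
        for (int iz = cz - wz; iz <= cz + wz + 1; ++iz) {
          double dz = (iz - uz) * hz;
          double d2 = d2xy + dz * dz;
          if (d2 > rad * rad) continue;
          int jz = ((iz % nz) + nz) % nz;
          double w = std::exp(-d2 * inv2s2);
          wsum += w;
          weights.push_back(w);
          idx.push_back(grid_index(jx, jy, jz, ny, nz));
        }
      }
    }
    if (wsum <= 0) stop("charge assignment: empty spreading support");
    double s = q[a] / (wsum * vox);
    for (size_t t = 0; t < weights.size(); ++t) rho[idx[t]] += s * weights[t];
  }
  return rho;
}
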