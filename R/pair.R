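# Pair laws and the direct-sum reference backend.

#' Lorentz-Berthelot mixing for Morse parameters
#'
#' Combines per-atom well depths by geometric mean and radii by sum, so that
#' the mixed equilibrium distance is `R_i + R_j`.
#'
#' @param eps_i,R_i,eps_j,R_j per-atom well depths (eV) and radii (Angstrom);
#'   vectorized.
#' @return list with `eps` (eV) and `R` (Angstrom).
#' @export
mix_lb <- function(eps_i, R_i, eps_j, R_j) {
  if (any(eps_i < 0) || any(eps_j < 0)) stop("mix_lb: negative well depth")
  if (any(R_i <= 0) || any(R_j <= 0)) stop("mix_lb: nonpositive radius")
  list(eps = sqrt(eps_i * eps_j), R = R_i + R_j)
}

#' Morse pair energy and radial derivative
#'
#' \deqn{E(r) = \epsilon (e^{-2\alpha(r - R)} - 2 e^{-\alpha(r - R)})}
#' with the analytic derivative returned alongside; the minimum is
#' \eqn{E(R) = -\epsilon}.
#'
#' @param r separation(s), Angstrom (> 0).
#' @param eps mixed well depth, eV.
#' @param R mixed equilibrium distance, Angstrom.
#' @param alpha stiffness, 1/Angstrom.
#' @return list with `E` (eV) and `dE_dr` (eV/Angstrom).
#' @export
morse_pair <- function(r, eps, R, alpha = 1.5) {
  cpp_morse_pair(as.numeric(r), eps, R, alpha)
}

# Expand substrate atoms over lateral periodic images (-n..n on each
# periodic lateral axis).  Returns positions plus replicated parameters.
expand_images <- function(sub, n_images) {
  pos <- atom_positions(sub)
  a <- sub$lattice[1, ]; b <- sub$lattice[2, ]
  ia <- if (sub$periodic[1]) -n_images:n_images else 0L
  ib <- if (sub$periodic[2]) -n_images:n_images else 0L
  shifts <- as.matrix(expand.grid(ia = ia, ib = ib))
  m <- nrow(shifts); n <- nrow(pos)
  spos <- matrix(0, n * m, 3)
  for (s in seq_len(m)) {
    off <- shifts[s, 1] * a + shifts[s, 2] * b
    spos[((s - 1) * n + 1):(s * n), ] <- sweep(pos, 2, -off)
  }
  list(pos = spos, eps = rep(sub$atoms$eps, m), R = rep(sub$atoms$R, m),
       q = rep(sub$atoms$q, m))
}

#' Direct pairwise-sum reference for molecule-substrate interactions
#'
#' The all-atom baseline every grid result is validated against: Morse terms
#' are summed explicitly over substrate atoms and their lateral periodic
#' images (truncated at the cutoff), Coulomb terms either over the same
#' image expansion (`coulomb = "images"`) or through the converged Ewald
#' summation (`coulomb = "ewald"`, default).  Forces are exact gradients of
#' the returned energy.
#'
#' @param mol a [molecule()] (or any object with an `atoms` frame).
#' @param sub a [substrate()].
#' @param params [global_params()].
#' @param n_images lateral image count per direction; default covers the
#'   cutoff.
#' @param coulomb `"ewald"` or `"images"`.
#' @param ewald optional precomputed [ewald_setup()] (built on demand).
#' @param pos optional replacement coordinates (n x 3 matrix).
#' @return list with `E_morse`, `E_coul` (eV) and `F` (n x 3, eV/Angstrom).
#' @export
direct_reference <- function(mol, sub, params = global_params(),
                             n_images = NULL, coulomb = c("ewald", "images"),
                             ewald = NULL, pos = NULL) {
  coulomb <- match.arg(coulomb)
  La <- sqrt(sum(sub$lattice[1, ]^2)); Lb <- sqrt(sum(sub$lattice[2, ]^2))
  if (is.null(n_images))
    n_images <- ceiling(params$r_cut / min(La, Lb)) + 1L
  if (any(sub$periodic[1:2]) && n_images * min(La, Lb) < params$r_cut)
    warning("lateral image extent smaller than the cutoff")
  img <- expand_images(sub, n_images)
  if (is.null(pos)) pos <- as.matrix(mol$atoms[, c("x", "y", "z")])
  m <- cpp_direct_morse(pos, mol$atoms$eps, mol$atoms$R, img$pos, img$eps,
                        img$R, params$alpha, params$r_cut)
  if (coulomb == "images") {
    cc <- cpp_direct_coulomb(pos, mol$atoms$q, img$pos, img$q)
    E_coul <- cc$E; F <- m$F + cc$F
  } else {
    if (is.null(ewald)) ewald <- ewald_setup(sub)
    ev <- ewald_eval(ewald, pos, grad = TRUE)
    E_coul <- sum(mol$atoms$q * ev$V)
    F <- m$F - mol$atoms$q * ev$G
  }
  list(E_morse = m$E, E_coul = E_coul, F = F)
}
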