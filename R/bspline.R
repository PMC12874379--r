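# Tricubic B-spline representation of the grid fields: coefficient fitting
# (gradient descent with an exact separable-prefilter reference path) and
# tensor-product evaluation with analytic gradients.

#' Cubic B-spline basis weights and derivatives
#'
#' The four uniform cubic B-spline basis values on the 4-node stencil for a
#' fractional offset `t` in `[0, 1)`, plus their derivatives with respect to
#' `t`.  Rows sum to 1 (partition of unity) and derivative rows sum to 0.
#'
#' @param t numeric vector of fractional offsets in `[0, 1)`.
#' @return list with matrices `w` and `dw` (length(t) x 4).
#' @export
bspline_weights <- function(t) cpp_bspline_weights(as.numeric(t))

#' Fit B-spline coefficients to a scalar field
#'
#' Finds coefficients `c` with `B c = f` (B = separable cubic B-spline
#' node-interpolation operator) so the interpolant reproduces every node
#' value.  `method = "descent"` runs fixed-step gradient descent on the SPD
#' quadratic whose stationary point is the interpolation condition
#' (initialized from the node values; B's spectrum lies in [1/27, 1], making
#' the iteration unconditionally convergent); `method = "prefilter"` solves
#' the same system exactly with 1D tridiagonal/cyclic solves per axis and
#' serves as the independent reference path.
#'
#' @param field a [scalar_field()].
#' @param max_iter iteration cap for the descent (default 3000).
#' @param tol stop when the node RMS residual falls below this (field
#'   units).
#' @param method `"descent"` or `"prefilter"`.
#' @return object of class `gridff_bspline` with the coefficient array and a
#'   `fit_report` (iterations, final RMS residual).
#' @export
fit_coeffs <- function(field, max_iter = 3000, tol = 1e-10,
                       method = c("descent", "prefilter")) {
  method <- match.arg(method)
  spec <- field$spec
  if (method == "descent") {
    out <- cpp_fit_descent(field$values, spec$dims, spec$periodic,
                           as.integer(max_iter), tol)
    coeffs <- out$coeffs
    report <- list(method = method, iterations = out$iterations,
                   rms = out$rms)
  } else {
    coeffs <- cpp_prefilter(field$values, spec$dims, spec$periodic)
    resid <- field$values - cpp_apply_interp_op(coeffs, spec$dims,
                                                spec$periodic)
    report <- list(method = method, iterations = 1L,
                   rms = sqrt(mean(resid^2)))
  }
  structure(list(coeffs = coeffs, spec = spec,
                 boundary = ifelse(spec$periodic, "periodic", "clamped"),
                 fit_report = report, unit = field$unit),
            class = "gridff_bspline")
}

#' @export
print.gridff_bspline <- function(x, ...) {
  cat(sprintf("gridff B-spline field (%s fit, %d iterations, node RMS %.3g)\n",
              x$fit_report$method, x$fit_report$iterations, x$fit_report$rms))
  print(x$spec)
  invisible(x)
}

#' Tricubic interpolation with analytic gradients
#'
#' Tensor-product evaluation over the 4 x 4 x 4 coefficient stencil (z
#' innermost, then y, then x); the returned gradient is the exact analytic
#' derivative of the interpolant.  Points outside the clamped-axis domain
#' raise an error (no silent extrapolation); periodic axes accept any
#' position after folding.
#'
#' @param field a `gridff_bspline` from [fit_coeffs()].
#' @param points n x 3 matrix (or length-3 vector), Angstrom.
#' @param grad if `FALSE`, skip gradients.
#' @return list with `value` (length n) and `gradient` (n x 3, field units
#'   per Angstrom).
#' @export
eval_tricubic <- function(field, points, grad = TRUE) {
  spec <- field$spec
  points <- matrix(as.numeric(points), ncol = 3)
  out <- cpp_eval_tricubic(list(field$coeffs), spec$dims, spec$origin,
                           spec$sinv, spec$periodic, points, grad)
  list(value = as.numeric(out$values[, 1]),
       gradient = if (grad) out$gradients[[1]] else NULL)
}

#' Fit all three components of a grid set
#'
#' @param gridset a `gridff_gridset` from [build_gridset()].
#' @param ... passed to [fit_coeffs()].
#' @return object of class `gridff_field`: the runtime interaction object
#'   holding the three fitted coefficient arrays.
#' @export
fit_gridset <- function(gridset, ...) {
  comps <- lapply(gridset[c("pauli", "london", "coulomb")], fit_coeffs, ...)
  structure(list(pauli = comps$pauli, london = comps$london,
                 coulomb = comps$coulomb, spec = comps$pauli$spec,
                 alpha = gridset$alpha, meta = gridset$meta),
            class = "gridff_field")
}

#' @export
print.gridff_field <- function(x, ...) {
  cat("gridff fitted interaction field\n")
  for (nm in c("pauli", "london", "coulomb"))
    cat(sprintf("  %-8s fit RMS %.3g (%d iterations)\n", nm,
                x[[nm]]$fit_report$rms, x[[nm]]$fit_report$iterations))
  print(x$spec)
  invisible(x)
}

# Factorization weights of an atom: the Morse energy against the substrate
# is wP * G_P - 2 wL * G_L with wP = sqrt(eps) e^{2 a R}, wL = sqrt(eps) e^{a R}.
atom_weights <- function(eps, R, alpha) {
  list(wP = sqrt(eps) * exp(2 * alpha * R), wL = sqrt(eps) * exp(alpha * R))
}

#' Energy and force of single atoms in the fitted field
#'
#' Combines the three interpolated components with the atom's factorization
#' weights and charge: `E = wP*G_P - 2*wL*G_L + q*V`, `F = -grad E`
#' (analytic).  Atoms above the grid top contribute zero (asymptotic
#' region); below the grid bottom is a domain error.
#'
#' @param field a `gridff_field` from [fit_gridset()].
#' @param eps_i,R_i,q_i atom parameters (vectorized).
#' @param pos n x 3 matrix (or length-3 vector) of positions, Angstrom.
#' @return list with `E` (summed total, eV), per-atom `E_morse` and
#'   `E_coul` vectors, and `F` (n x 3, eV/Angstrom).
#' @export
atom_energy_force <- function(field, eps_i, R_i, q_i, pos) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  n <- nrow(pos)
  eps_i <- rep_len(eps_i, n); R_i <- rep_len(R_i, n); q_i <- rep_len(q_i, n)
  w <- atom_weights(eps_i, R_i, field$alpha)
  out <- cpp_surf_grid(pos, w$wP, w$wL, q_i,
                       list(field$pauli$coeffs, field$london$coeffs,
                            field$coulomb$coeffs),
                       field$spec$dims, field$spec$origin, field$spec$sinv,
                       field$spec$periodic)
  list(E = sum(out$E_morse) + sum(out$E_coul),
       E_morse = as.numeric(out$E_morse), E_coul = as.numeric(out$E_coul),
       F = out$F)
}
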