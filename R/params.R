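# Per-element force-field constants and global parameters.

# Covalent radii (Angstrom, Cordero 2008) for bond perception and standard
# atomic masses (amu).  Nonbonded (eps, R) live in the editable parameter
# table under inst/extdata.
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                     Na = 1.66, Mg = 1.41, P = 1.07, S = 1.05, Cl = 1.02,
                     K = 2.03, Ca = 1.76, Br = 1.20)

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, Na = 22.990, Mg = 24.305, P = 30.974,
                    S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
                    Br = 79.904)

#' Global nonbonded parameters
#'
#' Container for the parameters shared by every Morse/Coulomb evaluation:
#' the Morse stiffness \eqn{\alpha}, the real-space cutoff and the Coulomb
#' constant.  Defaults follow the reference setup for ionic-surface
#' manipulation studies: \eqn{\alpha = 1.5} per Angstrom for all pairs and a
#' 17 Angstrom cutoff.
#'
#' @param alpha Morse stiffness, 1/Angstrom.
#' @param r_cut pairwise cutoff, Angstrom.
#' @param k_e Coulomb constant, eV*Angstrom/e^2.
#' @return an object of class `gridff_params`.
#' @export
global_params <- function(alpha = 1.5, r_cut = 17, k_e = .KE) {
  stopifnot(alpha > 0, r_cut > 0, k_e > 0)
  structure(list(alpha = alpha, r_cut = r_cut, k_e = k_e),
            class = "gridff_params")
}

#' Read a whitespace-delimited element parameter table
#'
#' Format: `element epsilon_eV R_angstrom charge_e`, `#` comments.  The
#' shipped default table carries standard UFF-derived well depths and radii
#' (R is half the UFF vdW distance, so that the pair equilibrium distance is
#' `R_i + R_j`) plus the nominal ionic charges used for rocksalt fixtures.
#'
#' @param path file path; default is the table shipped with the package.
#' @return data.frame with columns `element`, `eps`, `R`, `q`.
#' @export
read_param_table <- function(path = system.file("extdata", "uff_elements.dat",
                                                package = "gridff")) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("element", "eps", "R", "q"),
                    stringsAsFactors = FALSE)
  if (any(tab$eps < 0)) stop("parameter table: negative well depth")
  if (any(tab$R <= 0)) stop("parameter table: nonpositive radius")
  tab
}

#' Look up per-element nonbonded parameters
#'
#' @param elements character vector of element symbols.
#' @param table a parameter table from [read_param_table()].
#' @return data.frame with one row per input element (`eps`, `R`, `q`,
#'   `mass` in eV fs^2/A^2).
#' @export
element_params <- function(elements, table = read_param_table()) {
  idx <- match(elements, table$element)
  if (anyNA(idx)) {
    stop("unknown element(s) in parameter table: ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  mass <- .atomic_masses[elements]
  if (anyNA(mass)) {
    stop("no atomic mass for element(s): ",
         paste(unique(elements[is.na(mass)]), collapse = ", "))
  }
  data.frame(element = elements, eps = table$eps[idx], R = table$R[idx],
             q = table$q[idx], mass = unname(mass) * .AMU,
             stringsAsFactors = FALSE)
}

#' @export
print.gridff_params <- function(x, ...) {
  cat(sprintf("gridff global parameters: alpha = %g 1/A, r_cut = %g A, k_e = %g eV*A/e^2\n",
              x$alpha, x$r_cut, x$k_e))
  invisible(x)
}
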