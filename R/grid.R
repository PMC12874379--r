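# Grid specification, Morse-factor projection, charge assignment and the
# reciprocal-space Poisson solve.

#' Grid specification
#'
#' Nodes sit at `origin + i*da + j*db + k*dc`; on periodic axes the node
#' count spans the cell (node `n` wraps to node 0), on clamped axes `n`
#' nodes span `(n-1)*spacing`.  Storage is z-fastest contiguous.
#'
#' @param origin 3-vector, Angstrom.
#' @param spacing node spacing, Angstrom (equal on all axes).
#' @param dims integer node counts `(nx, ny, nz)` (>= 4 each).
#' @param lattice 3x3 matrix, rows = full grid span vectors.
#' @param periodic logical per-axis flags.
#' @return object of class `gridff_grid_spec`.
#' @export
grid_spec <- function(origin, spacing, dims, lattice, periodic) {
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, spacing > 0, length(dims) == 3,
            all(dims >= 4), all(dim(as.matrix(lattice)) == c(3, 3)),
            length(periodic) == 3)
  lattice <- as.matrix(lattice)
  for (d in 1:3) {
    span <- sqrt(sum(lattice[d, ]^2))
    nseg <- if (periodic[d]) dims[d] else dims[d] - 1L
    if (abs(span / nseg - spacing) > 1e-6)
      stop("grid_spec: axis ", d, " extent not commensurate with spacing")
  }
  step <- rbind(lattice[1, ] / ifelse(periodic[1], dims[1], dims[1] - 1L),
                lattice[2, ] / ifelse(periodic[2], dims[2], dims[2] - 1L),
                lattice[3, ] / ifelse(periodic[3], dims[3], dims[3] - 1L))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, lattice = lattice,
                 periodic = as.logical(periodic),
                 step = t(step),            # columns = da, db, dc
                 sinv = solve(t(step))),
            class = "gridff_grid_spec")
}

n_nodes <- function(spec) prod(spec$dims)

#' @export
print.gridff_grid_spec <- function(x, ...) {
  cat(sprintf("gridff grid: %d x %d x %d nodes at %.3g A spacing (%s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              paste(ifelse(x$periodic, "per", "clamp"), collapse = "/")))
  invisible(x)
}

#' Simulation-window grid over the substrate surface cell
#'
#' Builds the grid the interaction fields live on: laterally it spans one
#' substrate cell (periodic); vertically it is clamped between `z_lo` and
#' `z_hi` above the top atomic layer.
#'
#' @param sub a [substrate()].
#' @param spacing node spacing, Angstrom (default 0.1).
#' @param z_lo,z_hi grid window bounds along z, Angstrom (absolute
#'   coordinates; the fixture slabs put the top layer at z = 0).
#' @return a [grid_spec()].
#' @export
surface_grid_spec <- function(sub, spacing = 0.1, z_lo = 0.5, z_hi = 12) {
  La <- sqrt(sum(sub$lattice[1, ]^2)); Lb <- sqrt(sum(sub$lattice[2, ]^2))
  nx <- round(La / spacing); ny <- round(Lb / spacing)
  nz <- round((z_hi - z_lo) / spacing) + 1L
  lattice <- rbind(sub$lattice[1, ], sub$lattice[2, ],
                   c(0, 0, (nz - 1L) * spacing))
  grid_spec(c(0, 0, z_lo), spacing, c(nx, ny, nz), lattice,
            c(TRUE, TRUE, FALSE))
}

#' Scalar field on a grid
#'
#' @param spec a [grid_spec()].
#' @param values numeric vector, z-fastest order, length `prod(dims)`.
#' @param unit free-text unit label.
#' @return object of class `gridff_field1`.
#' @export
scalar_field <- function(spec, values, unit = "") {
  stopifnot(inherits(spec, "gridff_grid_spec"),
            length(values) == n_nodes(spec))
  if (!all(is.finite(values))) stop("scalar_field: non-finite values")
  structure(list(spec = spec, values = as.numeric(values), unit = unit),
            class = "gridff_field1")
}

#' Fold positions into the periodic cell
#'
#' Maps fractional coordinates into `[0, 1)` on periodic axes; other axes
#' are untouched.  Idempotent.
#'
#' @param pos n x 3 matrix (or length-3 vector), Angstrom.
#' @param lattice 3x3 matrix, rows = cell vectors.
#' @param periodic logical per-axis flags.
#' @return folded positions, same shape as input.
#' @export
map_into_cell <- function(pos, lattice, periodic = c(TRUE, TRUE, FALSE)) {
  v <- is.null(dim(pos))
  pos <- matrix(as.numeric(pos), ncol = 3)
  tmat <- t(as.matrix(lattice))
  u <- pos %*% t(solve(tmat))
  for (d in 1:3) if (periodic[d]) u[, d] <- u[, d] - floor(u[, d])
  out <- u %*% t(tmat)
  if (v) drop(out) else out
}

#' Project the factorized Morse components onto a grid
#'
#' Computes the Pauli and London inner sums over all substrate atoms and
#' their lateral periodic images within the cutoff:
#' \deqn{G_P(r) = \sum_j \sqrt{\epsilon_j}\, e^{-2\alpha(|r - r_j| - R_j)},
#'       \quad
#'       G_L(r) = \sum_j \sqrt{\epsilon_j}\, e^{-\alpha(|r - r_j| - R_j)}.}
#' A probe atom's Morse energy is then
#' \eqn{\sqrt{\epsilon_i} e^{2\alpha R_i} G_P - 2 \sqrt{\epsilon_i}
#' e^{\alpha R_i} G_L}, identical to the direct pair sum.
#'
#' @param sub a [substrate()].
#' @param spec a [grid_spec()].
#' @param params [global_params()].
#' @return list with `pauli` and `london` [scalar_field()]s.
#' @export
project_morse_components <- function(sub, spec, params = global_params()) {
  La <- sqrt(sum(sub$lattice[1, ]^2)); Lb <- sqrt(sum(sub$lattice[2, ]^2))
  n_img <- ceiling(params$r_cut / min(La, Lb)) + 1L
  img <- expand_images(sub, n_img)
  out <- cpp_project_morse(img$pos, img$eps, img$R, spec$origin, spec$step,
                           spec$dims, params$alpha, params$r_cut)
  list(pauli = scalar_field(spec, out$pauli, "sqrt(eV)"),
       london = scalar_field(spec, out$london, "sqrt(eV)"))
}

#' Fully periodic grid for the Poisson solve
#'
#' The electrostatic solve runs on a 3D-periodic grid with vacuum padding
#' along z; its z nodes are aligned with the simulation window so the
#' solved potential can be cropped node-for-node.
#'
#' @param sub a [substrate()].
#' @param window the simulation-window [grid_spec()] (for alignment).
#' @param pad_below,pad_above vacuum padding, Angstrom (values are rounded
#'   to whole node spacings).
#' @return a fully periodic [grid_spec()].
#' @export
poisson_grid_spec <- function(sub, window, pad_below = 6, pad_above = 16) {
  h <- window$spacing
  zmin_atom <- min(sub$atoms$z)
  z_lo <- window$origin[3]
  n_below <- ceiling((z_lo - zmin_atom + pad_below) / h)
  z0 <- z_lo - n_below * h
  z_top_win <- z_lo + (window$dims[3] - 1L) * h
  n_total <- n_below + (window$dims[3] - 1L) +
    ceiling(pad_above / h)
  lattice <- rbind(window$lattice[1, ], window$lattice[2, ],
                   c(0, 0, n_total * h))
  grid_spec(c(0, 0, z0), h, c(window$dims[1], window$dims[2], n_total),
            lattice, c(TRUE, TRUE, TRUE))
}

#' Assign point charges to a periodic grid as a Gaussian charge density
#'
#' Each charge is spread as a normalized Gaussian of width `sigma`
#' (truncated at `trunc * sigma` and renormalized so every atom deposits
#' exactly its charge).  With the reciprocal-space Poisson solve this makes
#' the grid potential the Ewald reciprocal-space potential for splitting
#' \eqn{\beta = 1/(\sigma\sqrt{2})}, whose real-space residual is negligible
#' beyond \eqn{\sim 6\sigma}.
#'
#' @param sub a neutral [substrate()].
#' @param spec a fully periodic [grid_spec()] (see [poisson_grid_spec()]).
#' @param sigma Gaussian width, Angstrom.
#' @param trunc truncation radius in units of `sigma`.
#' @return charge density [scalar_field()], e/Angstrom^3.
#' @export
assign_charge_density <- function(sub, spec, sigma = 0.3, trunc = 6.5) {
  if (abs(sum(sub$atoms$q)) > 1e-10)
    stop("assign_charge_density: substrate not neutral")
  if (!all(spec$periodic))
    stop("assign_charge_density: Poisson grid must be periodic on all axes")
  if (max(abs(spec$step[row(spec$step) != col(spec$step)])) > 1e-9)
    stop("assign_charge_density: Poisson grid axes must be orthogonal")
  pos <- atom_positions(sub)
  zlo <- spec$origin[3]; zhi <- zlo + spec$dims[3] * spec$spacing
  if (any(pos[, 3] < zlo | pos[, 3] > zhi))
    stop("assign_charge_density: atom outside grid bounds")
  rho <- cpp_assign_gaussian(pos, sub$atoms$q, spec$origin, spec$step,
                             spec$dims, sigma, trunc)
  scalar_field(spec, rho, "e/A^3")
}

#' Solve the Poisson equation in reciprocal space
#'
#' FFT-based solve of \eqn{\nabla^2 V = -4\pi k_e \rho} on a fully periodic
#' grid: \eqn{V(k) = 4\pi k_e \rho(k)/|k|^2}, with the k = 0 mode set to
#' zero (tin-foil convention; requires a neutral density).
#'
#' @param rho charge density [scalar_field()] on a periodic grid (e/A^3).
#' @param k_e Coulomb constant, eV*Angstrom/e^2.
#' @return potential [scalar_field()], eV/e.
#' @export
solve_poisson_reciprocal <- function(rho, k_e = .KE) {
  spec <- rho$spec
  if (!all(spec$periodic))
    stop("solve_poisson_reciprocal: grid must be periodic on all axes")
  vox <- abs(det(spec$step))
  total <- sum(rho$values) * vox
  if (abs(total) > 1e-8)
    stop("solve_poisson_reciprocal: density not neutral (k = 0 divergence)")
  nx <- spec$dims[1]; ny <- spec$dims[2]; nz <- spec$dims[3]
  # z-fastest storage maps onto an array with dim (nz, ny, nx)
  arr <- array(rho$values, dim = c(nz, ny, nx))
  rhat <- fft(arr)
  freq <- function(n, L) {
    m <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n]
    2 * pi * m / L
  }
  Lx <- sqrt(sum(spec$lattice[1, ]^2))
  Ly <- sqrt(sum(spec$lattice[2, ]^2))
  Lz <- sqrt(sum(spec$lattice[3, ]^2))
  kz <- freq(nz, Lz); ky <- freq(ny, Ly); kx <- freq(nx, Lx)
  k2 <- outer(kz^2, ky^2, "+")
  k2 <- outer(k2, kx^2, "+")
  k2[1, 1, 1] <- Inf                      # drop k = 0
  vhat <- 4 * pi * k_e * rhat / k2
  V <- Re(fft(vhat, inverse = TRUE)) / length(vhat)
  scalar_field(spec, as.numeric(V), "eV/e")
}

# Crop a field on the periodic Poisson grid to the clamped simulation
# window (node-aligned along z).
crop_field_to_window <- function(field, window) {
  spec <- field$spec
  h <- spec$spacing
  off <- round((window$origin[3] - spec$origin[3]) / h)
  stopifnot(abs(window$origin[3] - (spec$origin[3] + off * h)) < 1e-8,
            off >= 0, off + window$dims[3] <= spec$dims[3],
            all(window$dims[1:2] == spec$dims[1:2]))
  nz <- spec$dims[3]; ny <- spec$dims[2]; nx <- spec$dims[1]
  arr <- array(field$values, dim = c(nz, ny, nx))
  sub <- arr[(off + 1):(off + window$dims[3]), , , drop = FALSE]
  scalar_field(window, as.numeric(sub), field$unit)
}

# Cheap deterministic content hash (FNV-1a over a rounded text rendering)
# used for provenance metadata.
content_hash <- function(...) {
  txt <- paste(vapply(list(...), function(x)
    paste(sprintf("%.10g", as.numeric(unlist(x))), collapse = ","),
    character(1)), collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build the full grid set for a substrate
#'
#' Pipeline: Morse-factor projection on the simulation window, Gaussian
#' charge assignment and reciprocal-space Poisson solve on the padded
#' periodic grid, then cropping of the potential back to the window.
#' Deterministic; provenance metadata (substrate hash, cutoff, spacing) is
#' recorded.
#'
#' @param sub a neutral [substrate()].
#' @param spec the simulation-window [grid_spec()]; default from
#'   [surface_grid_spec()].
#' @param params [global_params()].
#' @param sigma charge-smearing width, Angstrom.
#' @param pad_below,pad_above Poisson vacuum padding, Angstrom.
#' @return object of class `gridff_gridset` with fields `pauli`, `london`,
#'   `coulomb`.
#' @export
build_gridset <- function(sub, spec = NULL, params = global_params(),
                          sigma = 0.3, pad_below = 6, pad_above = 16) {
  if (is.null(spec)) spec <- surface_grid_spec(sub)
  morse <- project_morse_components(sub, spec, params)
  pspec <- poisson_grid_spec(sub, spec, pad_below, pad_above)
  rho <- assign_charge_density(sub, pspec, sigma = sigma)
  Vfull <- solve_poisson_reciprocal(rho, params$k_e)
  coulomb <- crop_field_to_window(Vfull, spec)
  structure(list(pauli = morse$pauli, london = morse$london,
                 coulomb = coulomb, alpha = params$alpha,
                 meta = list(substrate_hash = content_hash(
                               atom_positions(sub), sub$atoms$q,
                               sub$atoms$eps, sub$atoms$R, sub$lattice),
                             r_cut = params$r_cut, spacing = spec$spacing,
                             sigma = sigma, date = format(Sys.time(),
                                                          "%Y-%m-%d"))),
            class = "gridff_gridset")
}

#' @export
print.gridff_gridset <- function(x, ...) {
  print(x$pauli$spec)
  cat(sprintf("  components: pauli/london/coulomb, alpha = %g 1/A, substrate %s\n",
              x$alpha, x$meta$substrate_hash))
  invisible(x)
}
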