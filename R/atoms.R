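# Domain types: substrates (rigid periodic slabs) and molecules (flexible
# adsorbates with bonded topology), plus the built-in fixture generators.

.as_atom_frame <- function(atoms) {
  need <- c("element", "x", "y", "z", "q", "eps", "R")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  if (any(atoms$eps < 0)) stop("well depth eps must be >= 0")
  if (any(atoms$R <= 0)) stop("radius R must be > 0")
  atoms
}

#' Rigid substrate
#'
#' A rigid list of atoms with lattice vectors and per-axis periodicity
#' (x, y periodic, z open for slabs).  The substrate is the only input the
#' interaction grids are built from.
#'
#' @param atoms data.frame with columns `element, x, y, z, q, eps, R`.
#' @param lattice 3x3 matrix, rows = cell vectors (Angstrom).
#' @param periodic logical length-3 per-axis flags.
#' @return object of class `gridff_substrate`.
#' @export
substrate <- function(atoms, lattice, periodic = c(TRUE, TRUE, FALSE)) {
  atoms <- .as_atom_frame(atoms)
  lattice <- as.matrix(lattice)
  stopifnot(all(dim(lattice) == c(3, 3)), length(periodic) == 3)
  if (abs(det(lattice)) < 1e-9)
    stop("lattice rows must be linearly independent")
  structure(list(atoms = atoms, lattice = lattice,
                 periodic = as.logical(periodic)),
            class = "gridff_substrate")
}

#' @export
print.gridff_substrate <- function(x, ...) {
  cat(sprintf("gridff substrate: %d atoms (%s), net charge %+.3f e\n",
              nrow(x$atoms),
              paste(names(table(x$atoms$element)), collapse = "/"),
              sum(x$atoms$q)))
  cat("  lattice (rows, A):\n")
  print(round(x$lattice, 4))
  invisible(x)
}

atom_positions <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

#' Build a rocksalt (NaCl-type) (001) slab fixture
#'
#' The surface unit cell is an `a` x `a` square holding one Na and one Cl per
#' layer (Na at the origin, Cl at the cell centre); layers are stacked at
#' `a/2` with alternating registry so that cations sit above anions.  The top
#' layer is at z = 0 and the slab extends downwards, so heights above the
#' surface are plain z coordinates.  An 8 x 8 x 3 slab has 384 atoms, a
#' 20 x 20 x 3 slab 2400.
#'
#' @param nx,ny lateral repetitions of the surface cell.
#' @param nlayers number of atomic layers.
#' @param a surface lattice spacing, Angstrom (default 4.0).
#' @param qNa,qCl ion charges in e (must be opposite; defaults +-0.9).
#' @param table element parameter table for (eps, R).
#' @return a [substrate()].
#' @export
build_rocksalt_slab <- function(nx, ny, nlayers, a = 4.0, qNa = 0.9,
                                qCl = -0.9, table = read_param_table()) {
  stopifnot(nx >= 1, ny >= 1, nlayers >= 1, a > 0)
  if (qNa != -qCl) stop("non-neutral parameterization: qNa must equal -qCl")
  pna <- element_params("Na", table)
  pcl <- element_params("Cl", table)
  rows <- vector("list", 2L * nx * ny * nlayers)
  n <- 0L
  for (layer in seq_len(nlayers) - 1L) {
    zz <- -layer * a / 2
    shift <- if (layer %% 2L == 1L) a / 2 else 0
    for (ix in seq_len(nx) - 1L) {
      for (iy in seq_len(ny) - 1L) {
        x0 <- ix * a + shift
        y0 <- iy * a + shift
        rows[[n <- n + 1L]] <- data.frame(
          element = "Na", x = x0 %% (nx * a), y = y0 %% (ny * a), z = zz,
          q = qNa, eps = pna$eps, R = pna$R, stringsAsFactors = FALSE)
        rows[[n <- n + 1L]] <- data.frame(
          element = "Cl", x = (x0 + a / 2) %% (nx * a),
          y = (y0 + a / 2) %% (ny * a), z = zz,
          q = qCl, eps = pcl$eps, R = pcl$R, stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  lattice <- diag(c(nx * a, ny * a, max(nlayers * a / 2, a)))
  substrate(atoms, lattice, periodic = c(TRUE, TRUE, FALSE))
}

#' Remove a neutral Na-Cl vacancy pair from the topmost layer
#'
#' Removes the nearest-neighbour cation/anion pair of the top atomic layer
#' closest to the lateral cell centre, leaving the slab neutral.
#'
#' @param sub a rocksalt [substrate()].
#' @return the substrate with two atoms removed.
#' @export
introduce_vacancy_pair <- function(sub) {
  at <- sub$atoms
  ztop <- max(at$z)
  top <- which(abs(at$z - ztop) < 1e-6)
  pos <- which(at$q[top] > 0)
  neg <- which(at$q[top] < 0)
  if (length(pos) == 0 || length(neg) == 0)
    stop("cannot find adjacent opposite-charge pair in the top layer")
  ptop <- as.matrix(at[top, c("x", "y", "z")])
  # nearest-neighbour +- distance in the top layer
  dmin <- Inf
  for (i in pos) {
    d <- sqrt(rowSums((ptop[neg, , drop = FALSE] -
                       matrix(ptop[i, ], length(neg), 3, byrow = TRUE))^2))
    dmin <- min(dmin, min(d))
  }
  centre <- c(sum(sub$lattice[1, 1:2]) / 2, sum(sub$lattice[2, 1:2]) / 2)
  best <- NULL; bestd <- Inf
  for (i in pos) {
    for (j in neg) {
      dij <- sqrt(sum((ptop[i, ] - ptop[j, ])^2))
      if (dij > dmin + 1e-6) next
      mid <- (ptop[i, 1:2] + ptop[j, 1:2]) / 2
      dc <- sum((mid - centre)^2)
      if (dc < bestd) { bestd <- dc; best <- c(i, j) }
    }
  }
  if (is.null(best))
    stop("cannot find adjacent opposite-charge pair in the top layer")
  drop_idx <- top[best]
  out <- sub
  out$atoms <- at[-drop_idx, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

# Derive angles, torsions and 1-2/1-3 exclusions from a bond list.
derive_topology <- function(bonds, n_atoms) {
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0 && (min(bonds) < 1 || max(bonds) > n_atoms))
    stop("bond indices out of range")
  nb <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  angles <- list(); torsions <- list()
  for (j in seq_len(n_atoms)) {
    ns <- sort(nb[[j]])
    if (length(ns) >= 2) {
      cmb <- utils::combn(ns, 2)
      for (c_ in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- c(cmb[1, c_], j, cmb[2, c_])
    }
  }
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in nb[[j]]) {
      if (i == k) next
      for (l in nb[[k]]) {
        if (l == j || l == i) next
        torsions[[length(torsions) + 1L]] <- c(i, j, k, l)
      }
    }
  }
  excl <- rbind(bonds,
                if (length(angles))
                  t(vapply(angles, function(a) c(a[1], a[3]), numeric(2))))
  if (!is.null(excl) && nrow(excl) > 0) {
    excl <- t(apply(excl, 1, sort))
    excl <- unique(excl)
  } else excl <- matrix(numeric(0), 0, 2)
  list(angles = if (length(angles)) do.call(rbind, angles)
                else matrix(0L, 0, 3),
       torsions = if (length(torsions)) do.call(rbind, torsions)
                  else matrix(0L, 0, 4),
       exclusions = excl)
}

#' Flexible molecule with bonded topology
#'
#' @param atoms data.frame with `element, x, y, z, q, eps, R` (mass added
#'   automatically).
#' @param bonds data.frame/matrix with columns `i, j` and optional `k`
#'   (eV/A^2) and `r0` (Angstrom); defaults k = 30, r0 = current length.
#' @param angle_k,angle_theta0 harmonic angle constants (eV/rad^2, rad);
#'   angles/torsions/exclusions are derived from the bond graph.
#' @param torsion_k length-3 cosine-series amplitudes (eV).
#' @param torsion_gamma length-3 phases (rad).
#' @return object of class `gridff_molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, angle_k = 3.0,
                     angle_theta0 = NULL, torsion_k = c(0.002, 0, 0.01),
                     torsion_gamma = c(0, 0, 0)) {
  atoms <- .as_atom_frame(atoms)
  n <- nrow(atoms)
  if (is.null(atoms$mass))
    atoms$mass <- unname(.atomic_masses[atoms$element]) * .AMU
  if (anyNA(atoms$mass)) stop("unknown element mass")
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0), k = numeric(0),
                        r0 = numeric(0))
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:2] <- c("i", "j")
    if (is.null(bonds$k)) bonds$k <- 30
    if (is.null(bonds$r0)) {
      p <- as.matrix(atoms[, c("x", "y", "z")])
      bonds$r0 <- sqrt(rowSums((p[bonds$i, , drop = FALSE] -
                                p[bonds$j, , drop = FALSE])^2))
    }
  }
  topo <- derive_topology(bonds[, c("i", "j"), drop = FALSE], n)
  ang <- topo$angles
  p <- as.matrix(atoms[, c("x", "y", "z")])
  th0 <- if (!is.null(angle_theta0)) rep(angle_theta0, NROW(ang)) else
    vapply(seq_len(NROW(ang)), function(a) {
      u <- p[ang[a, 1], ] - p[ang[a, 2], ]
      v <- p[ang[a, 3], ] - p[ang[a, 2], ]
      acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    }, numeric(1))
  tor <- topo$torsions
  mol <- structure(list(
    atoms = atoms,
    bonds = bonds,
    angles = if (NROW(ang)) data.frame(i = ang[, 1], j = ang[, 2],
                                       k = ang[, 3], k_th = angle_k,
                                       theta0 = th0)
             else data.frame(i = integer(0), j = integer(0), k = integer(0),
                             k_th = numeric(0), theta0 = numeric(0)),
    torsions = if (NROW(tor)) data.frame(i = tor[, 1], j = tor[, 2],
                                         k = tor[, 3], l = tor[, 4],
                                         k1 = torsion_k[1], k2 = torsion_k[2],
                                         k3 = torsion_k[3],
                                         g1 = torsion_gamma[1],
                                         g2 = torsion_gamma[2],
                                         g3 = torsion_gamma[3])
              else data.frame(i = integer(0), j = integer(0), k = integer(0),
                              l = integer(0)),
    exclusions = topo$exclusions), class = "gridff_molecule")
  validate_molecule(mol)
  mol
}

validate_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  idx <- c(mol$bonds$i, mol$bonds$j, unlist(mol$angles[, 1:3]),
           unlist(mol$torsions[, 1:4]), as.vector(mol$exclusions))
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    stop("molecule topology: atom index out of range")
  # every angle's outer pair must be an exclusion (1-3 consistency)
  if (nrow(mol$angles) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ek <- key(mol$exclusions[, 1], mol$exclusions[, 2])
    ak <- key(mol$angles$i, mol$angles$k)
    if (!all(ak %in% ek))
      stop("molecule topology inconsistent: angle outer pair not excluded")
  }
  invisible(mol)
}

#' @export
print.gridff_molecule <- function(x, ...) {
  cat(sprintf(
    "gridff molecule: %d atoms, %d bonds, %d angles, %d torsions, net charge %+.3f e\n",
    nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
    sum(x$atoms$q)))
  invisible(x)
}

#' Deterministic synthetic probe molecules
#'
#' Generates neutral probe adsorbates for scans and sampling: `rigid-planar`
#' (a planar carbon ring with alternating partial charges, meant to be used
#' rigidly), `flexible-chain` (a zig-zag carbon chain with rotatable
#' torsions) and `polyol-chain` (a chain with polar oxygen side groups,
#' hydrogen-bond-like charge pattern).  Geometry jitter is drawn from the
#' package's counter-based RNG, so equal seeds give identical molecules.
#'
#' @param kind one of `"rigid-planar"`, `"flexible-chain"`, `"polyol-chain"`.
#' @param n_atoms total atom count (>= 2).
#' @param seed integer seed.
#' @param table element parameter table.
#' @return a [molecule()].
#' @export
make_probe_molecule <- function(kind = c("flexible-chain", "rigid-planar",
                                         "polyol-chain"),
                                n_atoms = 8, seed = 1,
                                table = read_param_table()) {
  kind <- match.arg(kind)
  stopifnot(n_atoms >= 2)
  jit <- matrix(cpp_rng_normals(seed, 0, 0, 3L * n_atoms), ncol = 3) * 0.03
  alt_charge <- function(n, dq) {
    q <- rep(c(dq, -dq), length.out = n)
    if (n %% 2 == 1) q[n] <- 0
    q
  }
  if (kind == "rigid-planar") {
    n <- n_atoms
    rad <- 1.4 / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1) / n
    at <- data.frame(element = "C", x = rad * cos(th), y = rad * sin(th),
                     z = 0, q = alt_charge(n, 0.05), stringsAsFactors = FALSE)
    pc <- element_params("C", table)
    at$eps <- pc$eps; at$R <- pc$R
    bonds <- data.frame(i = seq_len(n), j = c(seq_len(n)[-1], 1))
    return(molecule(at, bonds, angle_k = 10, torsion_k = c(0, 0.05, 0)))
  }
  if (kind == "flexible-chain") {
    n <- n_atoms
    b <- 1.53; th <- 111 * pi / 180
    xs <- (seq_len(n) - 1) * b * sin(th / 2)
    ys <- rep(c(0, b * cos(th / 2)), length.out = n)
    at <- data.frame(element = "C", x = xs + jit[, 1], y = ys + jit[, 2],
                     z = jit[, 3], q = alt_charge(n, 0.1),
                     stringsAsFactors = FALSE)
    pc <- element_params("C", table)
    at$eps <- pc$eps; at$R <- pc$R
    bonds <- data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1,
                        k = 30, r0 = b)
    return(molecule(at, bonds, angle_k = 3, angle_theta0 = th,
                    torsion_k = c(0.002, 0, 0.01)))
  }
  # polyol-chain: carbon backbone with O side groups on alternating atoms
  nb <- ceiling(n_atoms * 2 / 3)
  no <- n_atoms - nb
  if (no < 1) { nb <- n_atoms - 1; no <- 1 }
  b <- 1.53; th <- 111 * pi / 180
  xs <- (seq_len(nb) - 1) * b * sin(th / 2)
  ys <- rep(c(0, b * cos(th / 2)), length.out = nb)
  hosts <- head(seq(1, nb, by = ifelse(no * 2 >= nb, 1, 2)), no)
  pc <- element_params("C", table); po <- element_params("O", table)
  at <- data.frame(element = rep("C", nb), x = xs, y = ys, z = 0,
                   q = 0, stringsAsFactors = FALSE)
  at$eps <- pc$eps; at$R <- pc$R
  bonds <- data.frame(i = seq_len(nb - 1), j = seq_len(nb - 1) + 1,
                      k = 30, r0 = b)
  for (t in seq_along(hosts)) {
    h <- hosts[t]
    side <- ifelse(t %% 2 == 0, 1, -1)
    at <- rbind(at, data.frame(element = "O", x = at$x[h],
                               y = at$y[h] + side * 0.3, z = 1.38,
                               q = -0.3, eps = po$eps, R = po$R,
                               stringsAsFactors = FALSE))
    at$q[h] <- 0.3
    bonds <- rbind(bonds, data.frame(i = h, j = nrow(at), k = 35, r0 = 1.43))
  }
  at$x <- at$x + jit[seq_len(nrow(at)), 1]
  at$y <- at$y + jit[seq_len(nrow(at)), 2]
  at$z <- at$z + jit[seq_len(nrow(at)), 3]
  molecule(at, bonds, angle_k = 3, torsion_k = c(0.002, 0, 0.01))
}
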