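# Energy/force assembly for a flexible adsorbate, FIRE relaxation, Langevin
# dynamics and the replica-batch contract.

#' Grid interaction backend
#'
#' @param field a `gridff_field` from [fit_gridset()].
#' @return backend object for [mm_system()].
#' @export
grid_backend <- function(field) {
  stopifnot(inherits(field, "gridff_field"))
  structure(list(type = "grid", field = field), class = "gridff_backend")
}

#' Direct-sum reference backend
#'
#' All-atom molecule-substrate interactions: Morse over lateral periodic
#' images within the cutoff, Coulomb through the converged Ewald tables.
#' Used to validate grid-backend results.
#'
#' @param sub a [substrate()].
#' @param params [global_params()].
#' @param ewald_tol Ewald accuracy target, eV/e.
#' @param beta Ewald splitting, 1/Angstrom.
#' @return backend object for [mm_system()].
#' @export
direct_backend <- function(sub, params = global_params(), ewald_tol = 1e-8,
                           beta = 1.0) {
  n_img <- ceiling(params$r_cut /
                   min(sqrt(sum(sub$lattice[1, ]^2)),
                       sqrt(sum(sub$lattice[2, ]^2)))) + 1L
  img <- expand_images(sub, n_img)
  ew <- ewald_setup(sub, beta = beta, tol = ewald_tol)
  tmat <- t(sub$lattice)
  structure(list(type = "direct", sub = sub, img = img, ewald = ew,
                 tmat = tmat, tinv = solve(tmat)),
            class = "gridff_backend")
}

#' Molecular-mechanics system
#'
#' Bundles a molecule, an interaction backend, optional fixed-atom
#' constraints and the global parameters.  Constrained atoms keep their
#' stored positions; their forces are zeroed after assembly.
#'
#' @param mol a [molecule()].
#' @param backend [grid_backend()] or [direct_backend()].
#' @param constraints integer vector of fixed atom indices (positions taken
#'   from the current geometry).
#' @param params [global_params()].
#' @return object of class `gridff_system`.
#' @export
mm_system <- function(mol, backend, constraints = integer(0),
                      params = global_params()) {
  stopifnot(inherits(mol, "gridff_molecule"),
            inherits(backend, "gridff_backend"))
  n <- nrow(mol$atoms)
  constraints <- as.integer(constraints)
  if (length(constraints) && (min(constraints) < 1 || max(constraints) > n))
    stop("constraint index out of range")
  # non-excluded intramolecular pair list
  pairs <- if (n >= 2) t(utils::combn(n, 2)) else matrix(0L, 0, 2)
  if (nrow(mol$exclusions) > 0 && nrow(pairs) > 0) {
    key <- paste(pairs[, 1], pairs[, 2])
    ek <- paste(pmin(mol$exclusions[, 1], mol$exclusions[, 2]),
                pmax(mol$exclusions[, 1], mol$exclusions[, 2]))
    pairs <- pairs[!(key %in% ek), , drop = FALSE]
  }
  structure(list(mol = mol, backend = backend, constraints = constraints,
                 params = params, nb_pairs = pairs,
                 pos = as.matrix(mol$atoms[, c("x", "y", "z")])),
            class = "gridff_system")
}

#' @export
print.gridff_system <- function(x, ...) {
  cat(sprintf("gridff system: %d-atom molecule on %s backend, %d constrained\n",
              nrow(x$mol$atoms), x$backend$type, length(x$constraints)))
  invisible(x)
}

set_positions <- function(system, pos) { system$pos <- pos; system }

#' Intramolecular energy and forces
#'
#' Harmonic bonds and angles, 3-term cosine torsions, plus intramolecular
#' nonbonded Morse + Coulomb over non-excluded (1-4 and beyond) pairs.  The
#' molecule is never periodically imaged.
#'
#' @param mol a [molecule()].
#' @param pos optional replacement coordinates.
#' @param params [global_params()].
#' @param nb_pairs optional precomputed pair list (internal).
#' @return list with `E_bonded`, `E_intra_nb`, `F`.
#' @export
intramolecular_energy_force <- function(mol, pos = NULL,
                                        params = global_params(),
                                        nb_pairs = NULL) {
  if (is.null(pos)) pos <- as.matrix(mol$atoms[, c("x", "y", "z")])
  n <- nrow(mol$atoms)
  if (is.null(nb_pairs)) {
    nb_pairs <- if (n >= 2) t(utils::combn(n, 2)) else matrix(0L, 0, 2)
    if (nrow(mol$exclusions) > 0 && nrow(nb_pairs) > 0) {
      key <- paste(nb_pairs[, 1], nb_pairs[, 2])
      ek <- paste(pmin(mol$exclusions[, 1], mol$exclusions[, 2]),
                  pmax(mol$exclusions[, 1], mol$exclusions[, 2]))
      nb_pairs <- nb_pairs[!(key %in% ek), , drop = FALSE]
    }
  }
  cpp_intramol(pos,
               as.matrix(mol$bonds[, c("i", "j")]) - 1L,
               mol$bonds$k, mol$bonds$r0,
               as.matrix(mol$angles[, c("i", "j", "k")]) - 1L,
               mol$angles$k_th, mol$angles$theta0,
               as.matrix(mol$torsions[, c("i", "j", "k", "l")]) - 1L,
               as.matrix(if (nrow(mol$torsions)) mol$torsions[, c("k1", "k2", "k3")]
                         else matrix(0, 0, 3)),
               as.matrix(if (nrow(mol$torsions)) mol$torsions[, c("g1", "g2", "g3")]
                         else matrix(0, 0, 3)),
               matrix(as.integer(nb_pairs), ncol = 2) - 1L,
               mol$atoms$eps, mol$atoms$R, mol$atoms$q,
               params$alpha, params$r_cut)
}

surface_energy_force <- function(system, pos) {
  be <- system$backend
  at <- system$mol$atoms
  if (be$type == "grid") {
    f <- be$field
    w <- atom_weights(at$eps, at$R, f$alpha)
    cpp_surf_grid(pos, w$wP, w$wL, at$q,
                  list(f$pauli$coeffs, f$london$coeffs, f$coulomb$coeffs),
                  f$spec$dims, f$spec$origin, f$spec$sinv, f$spec$periodic)
  } else {
    ew <- be$ewald
    cpp_surf_direct(pos, at$eps, at$R, at$q, be$img$pos, be$img$eps,
                    be$img$R, system$params$alpha, system$params$r_cut,
                    ew$kvec, ew$coef, ew$sre, ew$sim, ew$repos, ew$req,
                    ew$beta, ew$r_cut_real, be$tmat, be$tinv)
  }
}

#' Total energy and forces of a system
#'
#' Assembles the intramolecular terms and the molecule-substrate surface
#' terms from the active backend.  The energy decomposition (`bonded`,
#' `intra_nb`, `surf_morse`, `surf_coul`) sums to `total`; forces on
#' constrained atoms are zeroed.
#'
#' @param system an [mm_system()].
#' @param pos optional replacement coordinates (n x 3).
#' @return list with `E` (named components + `total`) and `F`.
#' @export
total_energy_force <- function(system, pos = NULL) {
  if (is.null(pos)) pos <- system$pos
  intra <- intramolecular_energy_force(system$mol, pos, system$params,
                                       system$nb_pairs)
  surf <- surface_energy_force(system, pos)
  F <- intra$F + surf$F
  if (length(system$constraints)) F[system$constraints, ] <- 0
  E <- list(bonded = intra$E_bonded, intra_nb = intra$E_intra_nb,
            surf_morse = sum(surf$E_morse), surf_coul = sum(surf$E_coul))
  E$total <- E$bonded + E$intra_nb + E$surf_morse + E$surf_coul
  list(E = E, F = F)
}

#' FIRE structural relaxation
#'
#' Fast inertial relaxation engine: damped dynamics that mixes velocities
#' toward the force direction while the system moves downhill and zeroes
#' them whenever the power `<F|v>` turns negative.  Parameters follow the
#' standard published defaults (`alpha_start = 0.1`, `f_inc = 1.1`,
#' `f_dec = 0.5`, `N_min = 5`, `f_alpha = 0.99`, `dt_max = 10 dt_init`).
#'
#' @param system an [mm_system()].
#' @param f_max convergence threshold on the per-atom force norm, eV/A.
#' @param max_steps step cap; reaching it returns `converged = FALSE`.
#' @param dt_init initial timestep, fs.
#' @param max_disp per-step displacement cap per coordinate, Angstrom.
#' @param settle after the force criterion is met, keep relaxing down to
#'   `settle * f_max` (or until `max_steps`) so the returned state is a
#'   well-defined basin minimizer rather than the first threshold
#'   crossing.  Soft (e.g. torsional) modes cross the bare threshold at
#'   trajectory-dependent phases; settling removes that noise, which
#'   matters for deterministic branch tracking in warm-started scans.
#'   `converged` always refers to `f_max` itself.
#' @return list with the updated `system`, `pos`, `converged`, `steps`,
#'   `energy` (decomposition at return) and `fmax`.
#' @export
fire_relax <- function(system, f_max = 1e-3, max_steps = 10000,
                       dt_init = 0.5, max_disp = 0.2, settle = 0.1) {
  pos <- system$pos
  n <- nrow(pos)
  mass <- matrix(system$mol$atoms$mass, n, 3)
  free <- setdiff(seq_len(n), system$constraints)
  v <- matrix(0, n, 3)
  dt <- dt_init; dt_max <- 10 * dt_init; dt_min <- 0.02 * dt_init
  a <- 0.1; a_start <- 0.1; f_inc <- 1.1; f_dec <- 0.5
  N_min <- 5L; f_a <- 0.99; cnt <- 0L
  ef <- total_energy_force(system, pos)
  E0 <- ef$E$total
  best_pos <- pos; best_E <- E0
  converged <- FALSE; steps <- 0L
  f_stop <- max(settle, 0) * f_max
  repeat {
    fmax <- if (length(free)) max(sqrt(rowSums(ef$F[free, , drop = FALSE]^2)))
            else 0
    if (fmax <= f_max) converged <- TRUE
    if (fmax <= f_stop || (converged && steps >= max_steps)) break
    if (steps >= max_steps) break
    P <- sum(ef$F * v)
    if (P > 0) {
      cnt <- cnt + 1L
      if (cnt > N_min) { dt <- min(dt * f_inc, dt_max); a <- a * f_a }
      vn <- sqrt(sum(v^2)); fn <- sqrt(sum(ef$F^2))
      if (fn > 0) v <- (1 - a) * v + a * vn * ef$F / fn
    } else {
      v[] <- 0; dt <- max(dt * f_dec, dt_min); a <- a_start; cnt <- 0L
    }
    v <- v + dt * ef$F / mass
    if (length(system$constraints)) v[system$constraints, ] <- 0
    dx <- dt * v
    over <- max(abs(dx))
    if (over > max_disp) dx <- dx * (max_disp / over)
    pos <- pos + dx
    ef <- total_energy_force(system, pos)
    if (ef$E$total < best_E) { best_E <- ef$E$total; best_pos <- pos }
    steps <- steps + 1L
  }
  if (ef$E$total > E0 && best_E <= E0) {  # guard: never return uphill
    pos <- best_pos
    ef <- total_energy_force(system, pos)
  }
  fmax <- {
    Ff <- ef$F; if (length(system$constraints)) Ff[system$constraints, ] <- 0
    if (length(free)) max(sqrt(rowSums(Ff[free, , drop = FALSE]^2))) else 0
  }
  list(system = set_positions(system, pos), pos = pos,
       converged = converged, steps = steps, energy = ef$E, fmax = fmax)
}

#' Replica batch for parallel-in-configuration sampling
#'
#' Independent replicas of one system sharing the (read-only) substrate
#' field; each replica owns its positions, velocities and a counter-based
#' RNG stream, so trajectories are reproducible and independent of the
#' replica count.
#'
#' @param system an [mm_system()].
#' @param n_replicas replica count.
#' @param seed base RNG seed (stream r = replica index).
#' @param init_pos a single n x 3 matrix or a list of per-replica matrices.
#' @return object of class `gridff_replicas`.
#' @export
make_replica_batch <- function(system, n_replicas, seed = 1,
                               init_pos = NULL) {
  if (is.null(init_pos)) init_pos <- system$pos
  pos <- if (is.list(init_pos)) init_pos else
    rep(list(init_pos), n_replicas)
  stopifnot(length(pos) == n_replicas)
  structure(list(system = system, n = n_replicas, seed = seed,
                 pos = pos, vel = rep(list(0 * pos[[1]]), n_replicas),
                 counter = rep(0, n_replicas),
                 failed = rep(FALSE, n_replicas)),
            class = "gridff_replicas")
}

#' Langevin dynamics over a replica batch
#'
#' BAOAB-split leapfrog integration with exact Ornstein-Uhlenbeck friction/
#' noise; with `gamma = 0, T = 0` it reduces to velocity Verlet (NVE).
#' Replicas evolve independently on their own counter-based noise streams;
#' a replica that turns non-finite is flagged failed and skipped while the
#' others continue.
#'
#' @param batch a [make_replica_batch()].
#' @param n_steps number of MD steps.
#' @param T temperature, K.
#' @param gamma friction, 1/fs.
#' @param dt timestep, fs.
#' @return the updated batch.
#' @export
run_langevin <- function(batch, n_steps, T = 300, gamma = 0.01, dt = 0.5) {
  system <- batch$system
  n <- nrow(system$pos)
  mass <- matrix(system$mol$atoms$mass, n, 3)
  cons <- system$constraints
  c1 <- exp(-gamma * dt)
  for (r in seq_len(batch$n)) {
    if (batch$failed[r]) next
    pos <- batch$pos[[r]]; v <- batch$vel[[r]]
    ef <- total_energy_force(system, pos)
    for (s in seq_len(n_steps)) {
      v <- v + 0.5 * dt * ef$F / mass
      pos <- pos + 0.5 * dt * v
      if (T > 0 && gamma > 0) {
        xi <- matrix(cpp_rng_normals(batch$seed, r, batch$counter[r] + s,
                                     3L * n), n, 3)
        v <- c1 * v + sqrt((1 - c1^2) * .KB * T / mass) * xi
      }
      pos <- pos + 0.5 * dt * v
      if (length(cons)) {
        pos[cons, ] <- batch$pos[[r]][cons, ]
        v[cons, ] <- 0
      }
      ef <- total_energy_force(system, pos)
      v <- v + 0.5 * dt * ef$F / mass
      if (!all(is.finite(pos))) break
    }
    if (!all(is.finite(pos)) || !all(is.finite(v))) {
      batch$failed[r] <- TRUE
    } else {
      batch$pos[[r]] <- pos; batch$vel[[r]] <- v
    }
    batch$counter[r] <- batch$counter[r] + n_steps
  }
  batch
}

#' @rdname run_langevin
#' @export
langevin_step <- function(batch, T = 300, gamma = 0.01, dt = 0.5) {
  run_langevin(batch, 1L, T = T, gamma = gamma, dt = dt)
}
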