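# Energy/force assembly, FIRE relaxation and Langevin dynamics.

test_that("intramolecular terms vanish at equilibrium and exclude 1-2 pairs", {
  at <- data.frame(element = "C", x = c(0, 1.53), y = 0, z = 0, q = 0,
                   eps = 0.0046, R = 1.93)
  mol <- molecule(at, bonds = data.frame(i = 1, j = 2))
  out <- intramolecular_energy_force(mol)
  expect_equal(out$E_bonded, 0, tolerance = 1e-14)
  expect_lt(max(abs(out$F)), 1e-12)
  # the bonded pair is excluded from nonbonded terms: cranking its Morse
  # depth changes nothing
  mol2 <- mol
  mol2$atoms$eps <- 10
  out2 <- intramolecular_energy_force(mol2)
  expect_equal(out2$E_intra_nb, 0, tolerance = 1e-14)
  expect_error(intramolecular_energy_force(
    mol, pos = matrix(c(0, 0, 0, 0, 0, 0), 2, 3)), "zero bond")
})

test_that("intramolecular forces are exact gradients on a random chain", {
  mol <- make_probe_molecule("flexible-chain", 8, seed = 3)
  pos <- as.matrix(mol$atoms[, c("x", "y", "z")])
  pos <- pos + 0.1 * matrix(sin(1:24), 8, 3)   # off-equilibrium
  out <- intramolecular_energy_force(mol, pos)
  fd <- num_grad(function(p) {
    o <- intramolecular_energy_force(mol, p)
    o$E_bonded + o$E_intra_nb
  }, pos)
  expect_lt(max(abs(out$F + fd)), 1e-6)
})

test_that("total energy decomposes consistently on both backends", {
  fld <- unit_field()
  sub <- unit_slab()
  mol <- make_probe_molecule("rigid-planar", 6, seed = 3)
  mol$atoms$x <- mol$atoms$x + 0.7
  mol$atoms$y <- mol$atoms$y + 0.3
  sys_g <- mm_system(mol, grid_backend(fld))
  sys_d <- mm_system(mol, unit_direct())
  p <- sys_g$pos
  p[, 3] <- p[, 3] + 3.5 - min(p[, 3])
  eg <- total_energy_force(sys_g, p)
  ed <- total_energy_force(sys_d, p)
  # decomposition sums to the total
  expect_equal(eg$E$total, with(eg$E, bonded + intra_nb + surf_morse +
                                        surf_coul), tolerance = 1e-12)
  # grid vs direct-sum backend component budgets for a rigid probe
  expect_lt(abs(eg$E$surf_morse - ed$E$surf_morse), 1e-6)
  expect_lt(abs(eg$E$surf_coul - ed$E$surf_coul), 1e-5)
  # far above the surface both surface components vanish
  pf <- p; pf[, 3] <- pf[, 3] + 25
  ef <- total_energy_force(sys_g, pf)
  expect_lt(abs(ef$E$surf_morse) + abs(ef$E$surf_coul), 1e-6)
  # below the grid bottom the domain error is explicit
  pb <- p; pb[1, 3] <- 0.2
  expect_error(total_energy_force(sys_g, pb), "below the grid")
})

test_that("constrained atoms keep zero force and fixed positions", {
  fld <- unit_field()
  mol <- make_probe_molecule("flexible-chain", 5, seed = 2)
  mol$atoms$z <- mol$atoms$z + 3
  sys <- mm_system(mol, grid_backend(fld), constraints = 2L)
  ef <- total_energy_force(sys)
  expect_true(all(ef$F[2, ] == 0))
  rr <- fire_relax(sys, f_max = 1e-3, max_steps = 2000)
  expect_equal(rr$pos[2, ], sys$pos[2, ], tolerance = 1e-14)
})

test_that("FIRE finds the analytic minima of simple systems", {
  fld <- unit_field()
  # 1D quadratic well: harmonic bond to a fixed partner
  at <- data.frame(element = "C", x = c(0, 1.9), y = 0, z = 30, q = 0,
                   eps = 1e-12, R = 1.93)
  mol <- molecule(at, bonds = data.frame(i = 1, j = 2, k = 20, r0 = 1.5))
  sys <- mm_system(mol, grid_backend(fld), constraints = 1L)
  rr <- fire_relax(sys, f_max = 1e-6)
  expect_true(rr$converged)
  expect_lt(abs(rr$pos[2, 1] - 1.5), 1e-4)
  # unconstrained Morse dimer relaxes to the mixed equilibrium distance
  at2 <- data.frame(element = "C", x = c(0, 3.1), y = 0, z = 30, q = 0,
                    eps = 0.0046, R = 1.93)
  dimer <- molecule(at2)
  sys2 <- mm_system(dimer, grid_backend(fld))
  r2 <- fire_relax(sys2, f_max = 1e-6)
  expect_true(r2$converged)
  expect_lt(abs(sqrt(sum((r2$pos[1, ] - r2$pos[2, ])^2)) - 2 * 1.93), 1e-3)
  # energy never ends above its starting value
  expect_lte(r2$energy$total, -1e-4)
})

test_that("relaxation from random starts lands on the PES minima found by grid search", {
  fld <- unit_field()
  at <- data.frame(element = "Na", x = 0, y = 0, z = 3.2, q = 0.3,
                   eps = 0.003, R = 1.6)
  mol <- molecule(at)
  sys <- mm_system(mol, grid_backend(fld))
  # exhaustive PES scan oracle over the cell at the relaxed height
  rel <- fire_relax(set_positions(sys, matrix(c(2, 2, 3), 1)), f_max = 1e-5)
  zmin <- rel$pos[1, 3]
  xs <- seq(0.05, 3.95, by = 0.05)
  E <- outer(xs, xs, function(x, y) {
    o <- atom_energy_force(fld, 0.003, 1.6, 0.3, cbind(x, y, zmin))
    o$E_morse + o$E_coul
  })
  gmin <- c(xs[which(E == min(E), arr.ind = TRUE)[1]],
            xs[which(E == min(E), arr.ind = TRUE)[2]])
  set.seed(21)
  ends <- matrix(0, 20, 3)
  for (k in 1:20) {
    start <- matrix(c(runif(2, 0, 4), runif(1, 2.8, 4)), 1)
    rk <- fire_relax(set_positions(sys, start), f_max = 1e-5,
                     max_steps = 20000)
    expect_true(rk$converged)
    expect_lte(rk$fmax, 1e-5)
    ends[k, ] <- map_into_cell(rk$pos, fld$spec$lattice)
  }
  # all end points sit on the grid-search minimum (one basin for +q: Cl top)
  d <- sqrt((ends[, 1] - gmin[1])^2 + (ends[, 2] - gmin[2])^2)
  expect_lt(max(d), 0.05)
})

test_that("NVE trajectories conserve energy with the spline backend", {
  fld <- unit_field()
  at <- data.frame(element = "C", x = c(1.1, 4.3), y = c(0.6, 0.9),
                   z = c(3.0, 3.4), q = c(0.1, -0.1), eps = 0.0046,
                   R = 1.93)
  mol <- molecule(at, bonds = data.frame(i = 1, j = 2, k = 5,
                                         r0 = sqrt(sum((at[1, 2:4] -
                                                        at[2, 2:4])^2))))
  sys <- mm_system(mol, grid_backend(fld))
  b <- make_replica_batch(sys, 1, seed = 3)
  b$vel[[1]][] <- 0.002                      # small kick
  mass <- matrix(mol$atoms$mass, 2, 3)
  etot <- function(b) total_energy_force(sys, b$pos[[1]])$E$total +
    sum(0.5 * mass * b$vel[[1]]^2)
  b <- run_langevin(b, 1000, T = 0, gamma = 0, dt = 0.25)
  E1 <- etot(b)
  b <- run_langevin(b, 4000, T = 0, gamma = 0, dt = 0.25)   # 1 ps more
  E2 <- etot(b)
  expect_lt(abs(E2 - E1), 1e-4)              # < 1e-4 eV / ps
})

test_that("Langevin thermostat equipartitions kinetic energy", {
  fld <- unit_field()
  at <- data.frame(element = "C", x = c(0, 1.53), y = 0, z = 30, q = 0,
                   eps = 0.0046, R = 1.93)
  mol <- molecule(at, bonds = data.frame(i = 1, j = 2))
  sys <- mm_system(mol, grid_backend(fld))          # free dimer, 6 dofs
  b <- make_replica_batch(sys, 1, seed = 7)
  mass <- matrix(mol$atoms$mass, 2, 3)
  ke <- 0; nsamp <- 0
  for (blk in 1:1200) {
    b <- run_langevin(b, 20, T = 300, gamma = 0.1, dt = 0.5)
    if (blk > 200) { ke <- ke + sum(0.5 * mass * b$vel[[1]]^2)
                     nsamp <- nsamp + 6 }
  }
  kBT2 <- 0.5 * 8.617333262e-5 * 300
  expect_lt(abs(ke / nsamp - kBT2) / kBT2, 0.05)
})

test_that("replica streams are deterministic and independent of batch size", {
  fld <- unit_field()
  at <- data.frame(element = "Na", x = 1, y = 1, z = 3.2, q = 0.3,
                   eps = 0.003, R = 1.6)
  sys <- mm_system(molecule(at), grid_backend(fld))
  b1 <- make_replica_batch(sys, 1, seed = 5)
  b2 <- make_replica_batch(sys, 3, seed = 5)
  b1 <- run_langevin(b1, 50)
  b2 <- run_langevin(b2, 50)
  # identical seed + stream => bitwise-identical trajectory
  expect_identical(b1$pos[[1]], b2$pos[[1]])
  # different streams actually differ
  expect_false(identical(b2$pos[[1]], b2$pos[[2]]))
  # single-step API advances the same stream
  b3 <- make_replica_batch(sys, 1, seed = 5)
  for (s in 1:50) b3 <- langevin_step(b3)
  expect_identical(b3$pos[[1]], b1$pos[[1]])
})
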