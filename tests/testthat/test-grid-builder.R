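# Morse-factor projection, charge assignment, reciprocal Poisson solve and
# periodic folding.

test_that("Morse projection matches closed forms and brute-force sums", {
  # single atom with eps = 1, R = 0: nodes at distance 1 give e^-3 / e^-1.5
  at <- data.frame(element = "C", x = 0, y = 0, z = 0, q = 0, eps = 1,
                   R = 1e-9)
  sub <- substrate(at, diag(c(60, 60, 60)), rep(FALSE, 3))
  spec <- grid_spec(c(-1, -1, 1), 0.5, c(5, 5, 5),
                    diag(c(2, 2, 2)), rep(FALSE, 3))
  pr <- project_morse_components(sub, spec)
  # node (ix=2, iy=2, iz=0) sits at (0, 0, 1)
  idx <- (2 * 5 + 2) * 5 + 0 + 1
  expect_equal(pr$pauli$values[idx], exp(-3), tolerance = 1e-8)
  expect_equal(pr$london$values[idx], exp(-1.5), tolerance = 1e-8)
  expect_true(all(pr$pauli$values >= 0), all(pr$london$values >= 0))

  # random substrate: 20 random nodes against per-node brute force
  rsub <- random_substrate(10)
  rspec <- grid_spec(c(1, 1, 2), 0.5, c(6, 6, 6), diag(c(2.5, 2.5, 2.5)),
                     rep(FALSE, 3))
  pp <- project_morse_components(rsub, rspec)
  spos <- as.matrix(rsub$atoms[, c("x", "y", "z")])
  set.seed(3)
  for (k in 1:20) {
    ii <- sample(0:5, 3, replace = TRUE)
    node <- c(1, 1, 2) + 0.5 * ii
    r <- sqrt(rowSums(sweep(spos, 2, node)^2))
    gp <- sum(sqrt(rsub$atoms$eps) * exp(-2 * 1.5 * (r - rsub$atoms$R)))
    gl <- sum(sqrt(rsub$atoms$eps) * exp(-1.5 * (r - rsub$atoms$R)))
    idx <- (ii[1] * 6 + ii[2]) * 6 + ii[3] + 1
    expect_lt(abs(pp$pauli$values[idx] - gp) / gp, 1e-12)
    expect_lt(abs(pp$london$values[idx] - gl) / gl, 1e-12)
  }
})

test_that("projected fields inherit substrate symmetry and lateral periodicity", {
  sub <- unit_slab()
  gs <- unit_gridset()
  nx <- gs$pauli$spec$dims[1]; ny <- gs$pauli$spec$dims[2]
  nz <- gs$pauli$spec$dims[3]
  arr <- array(gs$london$values, dim = c(nz, ny, nx))
  # mirror symmetry x <-> y (Na at (0,0), Cl at (2,2) lie on the diagonal)
  expect_lt(max(abs(arr - aperm(arr, c(1, 3, 2)))), 1e-12)
  # the projection sums over symmetric image sets: node row 0 equals what a
  # node at x = L would see (periodicity across the lateral boundary)
  vals <- eval_tricubic(fit_coeffs(gs$london), rbind(c(0.2, 1.3, 3),
                                                     c(0.2 + 4, 1.3, 3)))
  expect_lt(abs(diff(vals$value)), 1e-12)
})

test_that("Gaussian charge assignment conserves charge and translates on-grid", {
  sub <- unit_slab()
  win <- surface_grid_spec(sub, 0.2, 0.6, 6)
  pspec <- poisson_grid_spec(sub, win, 4, 8)
  rho <- assign_charge_density(sub, pspec)
  vox <- abs(det(pspec$step))
  expect_lt(abs(sum(rho$values) * vox), 1e-10)
  # per-atom charge conservation: +-q pair far apart along z
  pair <- substrate(data.frame(element = c("Na", "Cl"),
                               x = c(2, 2), y = c(2, 2), z = c(-1, -14),
                               q = c(0.9, -0.9), eps = 0.001, R = 1.5),
                    rbind(sub$lattice[1:2, ], c(0, 0, 40)), sub$periodic)
  win2 <- surface_grid_spec(pair, 0.2, 0.6, 6)
  p2 <- poisson_grid_spec(pair, win2, 4, 8)
  r2 <- assign_charge_density(pair, p2)
  vox2 <- abs(det(p2$step))
  # per-atom conservation: integrate the upper half (only the +q atom)
  nz <- p2$dims[3]; ny <- p2$dims[2]; nx <- p2$dims[1]
  arr <- array(r2$values, dim = c(nz, ny, nx))
  zcoord <- p2$origin[3] + (0:(nz - 1)) * p2$spacing
  upper <- zcoord > -8
  expect_equal(sum(arr[upper, , ]) * vox2, 0.9, tolerance = 1e-9)
  expect_lt(abs(sum(r2$values) * vox2), 1e-10)
  # shifting an atom by exactly one grid spacing shifts its footprint
  sh <- pair
  sh$atoms$x <- sh$atoms$x + 0.2
  r3 <- assign_charge_density(sh, p2)
  a3 <- array(r3$values, dim = c(nz, ny, nx))
  expect_lt(max(abs(a3[, , c(2:nx, 1)] - arr)), 1e-12)
})

test_that("reciprocal Poisson solve inverts the Laplacian mode by mode", {
  spec <- grid_spec(c(0, 0, 0), 0.5, c(16, 8, 8),
                    diag(c(8, 4, 4)), rep(TRUE, 3))
  # zero density -> zero potential
  z <- solve_poisson_reciprocal(scalar_field(spec, rep(0, 16 * 8 * 8)))
  expect_true(all(z$values == 0))
  # Fourier eigenmode: rho = cos(2 pi x / Lx)
  xcoord <- rep(0.5 * (0:15), each = 1)
  idx <- expand.grid(iz = 0:7, iy = 0:7, ix = 0:15)   # z-fastest order
  vals <- cos(2 * pi * (0.5 * idx$ix) / 8)
  # reorder into z-fastest storage: index = (ix*ny + iy)*nz + iz
  v <- numeric(16 * 8 * 8)
  v[(idx$ix * 8 + idx$iy) * 8 + idx$iz + 1] <- vals
  V <- solve_poisson_reciprocal(scalar_field(spec, v))
  kx <- 2 * pi / 8
  expected <- 4 * pi * 14.399645 * v / kx^2
  expect_lt(max(abs(V$values - expected)), 1e-9 * max(abs(expected)))
  # non-neutral density rejected
  expect_error(solve_poisson_reciprocal(scalar_field(spec,
                                                     rep(1, 16 * 8 * 8))),
               "neutral")
})

test_that("grid electrostatics matches the Ewald oracle between charges", {
  # two Gaussian-assigned charges in a periodic box: potential difference
  # between probe points matches the converged Ewald reference
  at <- data.frame(element = c("Na", "Cl"), x = c(4, 12), y = 8, z = 0,
                   q = c(0.9, -0.9), eps = 0.001, R = 1.5)
  box <- substrate(at, diag(c(16, 16, 16)), rep(TRUE, 3))
  spec <- grid_spec(c(0, 0, -8), 0.1, c(160, 160, 160),
                    diag(c(16, 16, 16)), rep(TRUE, 3))
  rho <- assign_charge_density(box, spec)
  V <- solve_poisson_reciprocal(rho)
  fld <- fit_coeffs(V, method = "prefilter")
  pts <- rbind(c(6.5, 8, 2.2), c(9.5, 8, -2.2))
  Vi <- eval_tricubic(fld, pts, grad = FALSE)$value
  ew <- ewald_setup(box, tol = 1e-10, pad_below = 8, pad_above = 8)
  Ve <- gridff:::ewald_eval(ew, pts)$V
  expect_lt(abs(diff(Vi) - diff(Ve)), 1e-5)   # < 0.01 meV e
})

test_that("gridset pipeline is deterministic and decays above the surface", {
  sub <- unit_slab()
  spec <- surface_grid_spec(sub, 0.2, 0.6, 10)
  g1 <- build_gridset(sub, spec)
  g2 <- build_gridset(sub, spec)
  expect_identical(g1$pauli$values, g2$pauli$values)
  expect_identical(g1$coulomb$values, g2$coulomb$values)
  expect_true(all(is.finite(g1$pauli$values)),
              all(is.finite(g1$coulomb$values)))
  # Coulomb magnitude at 8 A is far below its 3 A value (exponential decay
  # of the lateral harmonics); verified against the Ewald oracle too
  f <- fit_coeffs(g1$coulomb, method = "prefilter")
  v3 <- eval_tricubic(f, c(0, 0, 3), grad = FALSE)$value
  v8 <- eval_tricubic(f, c(0, 0, 8), grad = FALSE)$value
  expect_lt(abs(v8), 0.01 * abs(v3))
  expect_equal(v8, ewald_potential(sub, c(0, 0, 8)), tolerance = 1e-3)
})

test_that("map_into_cell folds, is idempotent and leaves z untouched", {
  lat <- diag(c(4, 4, 10))
  expect_equal(map_into_cell(c(4.4, -0.4, 3), lat), c(0.4, 3.6, 3),
               tolerance = 1e-12)
  p <- c(1.2, 3.9, -5)
  expect_equal(map_into_cell(p, lat), p)
  once <- map_into_cell(c(-7.3, 9.1, 2), lat)
  expect_equal(map_into_cell(once, lat), once, tolerance = 1e-12)
})
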