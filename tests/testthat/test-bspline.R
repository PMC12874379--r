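# Coefficient fitting and tricubic evaluation with analytic gradients.

test_that("cubic B-spline weights partition unity with consistent derivatives", {
  w0 <- bspline_weights(0)
  expect_equal(as.numeric(w0$w), c(1, 4, 1, 0) / 6)
  set.seed(2)
  t <- runif(50)
  bw <- bspline_weights(t)
  expect_lt(max(abs(rowSums(bw$w) - 1)), 1e-15)
  expect_lt(max(abs(rowSums(bw$dw))), 1e-14)
  h <- 1e-6
  fd <- (bspline_weights(t + h)$w - bspline_weights(t - h)$w) / (2 * h)
  expect_lt(max(abs(fd - bw$dw)), 1e-7)
  expect_error(bspline_weights(1.2), "t must be")
})

test_that("fitting reproduces constants and linear ramps exactly", {
  spec <- grid_spec(c(0, 0, 0), 0.5, c(8, 8, 8), diag(c(4, 4, 3.5)),
                    c(TRUE, TRUE, FALSE))
  cfit <- fit_coeffs(scalar_field(spec, rep(2.5, 512)))
  expect_lt(max(abs(cfit$coeffs - 2.5)), 1e-12)
  expect_lt(cfit$fit_report$rms, 1e-13)
  ev <- eval_tricubic(cfit, rbind(c(1.234, 2.21, 1.7)))
  expect_equal(ev$value, 2.5, tolerance = 1e-12)
  expect_lt(max(abs(ev$gradient)), 1e-12)
  # linear ramp along clamped z: node values are reproduced everywhere,
  # and the interpolant is linear away from the clamped edges
  spec2 <- grid_spec(c(0, 0, 0), 0.5, c(8, 8, 20), diag(c(4, 4, 9.5)),
                     c(TRUE, TRUE, FALSE))
  zlin <- rep(seq(0, 9.5, by = 0.5), times = 64)
  lfit <- fit_coeffs(scalar_field(spec2, zlin), tol = 1e-13)
  expect_lt(lfit$fit_report$rms, 1e-9)
  nodes <- rbind(c(0.5, 1, 0.5), c(1, 2, 5), c(2, 0, 9))
  evn <- eval_tricubic(lfit, nodes, grad = FALSE)
  expect_equal(evn$value, nodes[, 3], tolerance = 1e-9)
  evl <- eval_tricubic(lfit, rbind(c(0.7, 1.1, 4.77)))
  expect_equal(evl$value, 4.77, tolerance = 1e-5)
  expect_equal(as.numeric(evl$gradient), c(0, 0, 1), tolerance = 1e-4)
})

test_that("gradient descent and the exact prefilter agree", {
  # 12^3 toy field, mixed boundary conditions
  set.seed(5)
  spec <- grid_spec(c(0, 0, 0), 0.5, c(12, 12, 12),
                    diag(c(6, 6, 5.5)), c(TRUE, TRUE, FALSE))
  xs <- 0.5 * (0:11)
  f <- as.numeric(outer(outer(sin(2 * pi * xs / 6), cos(2 * pi * xs / 6),
                              function(a, b) a + b),
                        exp(-0.4 * xs), function(ab, c) ab * c))
  # reorder from x-fastest outer() layout into z-fastest storage
  arrx <- array(f, dim = c(12, 12, 12))          # [ix, iy, iz]
  fz <- as.numeric(aperm(arrx, c(3, 2, 1)))      # [iz, iy, ix]
  fld <- scalar_field(spec, fz)
  fit_gd <- fit_coeffs(fld, max_iter = 3000, tol = 0)
  fit_pf <- fit_coeffs(fld, method = "prefilter")
  expect_lt(fit_gd$fit_report$rms, 1e-12)
  expect_lt(fit_pf$fit_report$rms, 1e-12)
  expect_lt(max(abs(fit_gd$coeffs - fit_pf$coeffs)),
            10 * max(fit_gd$fit_report$rms, 1e-13))
  pts <- cbind(runif(1000, 0, 6), runif(1000, 0, 6), runif(1000, 0, 5.5))
  v1 <- eval_tricubic(fit_gd, pts, grad = FALSE)$value
  v2 <- eval_tricubic(fit_pf, pts, grad = FALSE)$value
  expect_lt(max(abs(v1 - v2)), 1e-8)
  # fitting is deterministic: refit gives identical coefficients
  expect_identical(fit_coeffs(fld, max_iter = 3000, tol = 0)$coeffs,
                   fit_gd$coeffs)
})

test_that("tricubic gradients match finite differences and wrap periodically", {
  fld <- unit_field()
  spec <- fld$spec
  set.seed(8)
  pts <- cbind(runif(100, -2, 6), runif(100, -2, 6), runif(100, 1, 11))
  for (comp in c("london", "coulomb")) {
    ev <- eval_tricubic(fld[[comp]], pts)
    h <- 1e-4
    for (d in 1:3) {
      pp <- pts; pp[, d] <- pp[, d] + h
      pm <- pts; pm[, d] <- pm[, d] - h
      fd <- (eval_tricubic(fld[[comp]], pp, grad = FALSE)$value -
             eval_tricubic(fld[[comp]], pm, grad = FALSE)$value) / (2 * h)
      expect_lt(max(abs(fd - ev$gradient[, d])), 1e-6)
    }
  }
  # periodic axes: x and x + Lx are identical
  p1 <- cbind(runif(20, 0, 4), runif(20, 0, 4), runif(20, 1, 11))
  p2 <- p1; p2[, 1] <- p2[, 1] + 4
  expect_lt(max(abs(eval_tricubic(fld$coulomb, p1, grad = FALSE)$value -
                    eval_tricubic(fld$coulomb, p2, grad = FALSE)$value)),
            1e-12)
  # out-of-domain along clamped z is an explicit error
  expect_error(eval_tricubic(fld$coulomb, c(1, 1, 12.6)), "domain")
  expect_error(eval_tricubic(fld$coulomb, c(1, 1, 0.1)), "domain")
})

test_that("atom energies in the field reduce to the pair laws", {
  # grid built for a two-ion cell: per-atom field energies vs the direct
  # pair sums (Morse) and the Ewald oracle (Coulomb)
  at <- data.frame(element = c("Na", "Cl"), x = c(6, 0), y = c(6, 0),
                   z = c(0, 0), q = c(0.9, -0.9), eps = c(0.003, 0.01),
                   R = c(1.49, 1.97))
  sub <- substrate(at, diag(c(12, 12, 30)), c(TRUE, TRUE, FALSE))
  spec <- surface_grid_spec(sub, 0.1, 1.5, 6)
  # a 12 A lateral cell needs deep vacuum padding (harmonics decay as
  # exp(-2 pi z / L)) for the z-periodic images to drop below 1e-5
  gs <- build_gridset(sub, spec, pad_above = 40)
  fld <- fit_gridset(gs)
  set.seed(11)
  ang <- runif(50, 0, 2 * pi); zz <- runif(50, 2.5, 5)
  rad <- runif(50, 0, 1.5)
  pts <- cbind(6 + rad * cos(ang), 6 + rad * sin(ang), zz)
  probe <- list(eps = 0.0046, R = 1.93, q = 0.25)
  out <- atom_energy_force(fld, probe$eps, probe$R, probe$q, pts)
  mixa <- mix_lb(probe$eps, probe$R, 0.003, 1.49)
  mixb <- mix_lb(probe$eps, probe$R, 0.01, 1.97)
  E_pair <- 0
  for (sx in -1:1) for (sy in -1:1) {
    r1 <- sqrt(rowSums(sweep(pts, 2, c(6 + 12 * sx, 6 + 12 * sy, 0))^2))
    r2 <- sqrt(rowSums(sweep(pts, 2, c(12 * sx, 12 * sy, 0))^2))
    E_pair <- E_pair + morse_pair(r1, mixa$eps, mixa$R, 1.5)$E +
      morse_pair(r2, mixb$eps, mixb$R, 1.5)$E
  }
  expect_lt(max(abs(out$E_morse - E_pair)), 1e-5)
  Ve <- ewald_potential(sub, pts, tol = 1e-9, pad_above = 40)
  expect_lt(max(abs(out$E_coul - probe$q * Ve)), 1e-5)
  # zero parameters give identically zero
  z0 <- atom_energy_force(fld, 0, 1.5, 0, pts[1:3, ])
  expect_identical(z0$E, 0)
  expect_true(all(z0$F == 0))
  # Morse part scales with sqrt(eps_i) (Lorentz-Berthelot factorization)
  e4 <- atom_energy_force(fld, 4 * probe$eps, probe$R, 0, pts[1:5, ])
  e1 <- atom_energy_force(fld, probe$eps, probe$R, 0, pts[1:5, ])
  expect_equal(e4$E_morse, 2 * e1$E_morse, tolerance = 1e-12)
})

test_that("field containers round-trip bitwise", {
  gs <- unit_gridset()
  fld <- unit_field()
  tmp <- tempfile(fileext = ".grid")
  write_gridset(gs, tmp)
  gs2 <- read_gridset(tmp)
  expect_identical(gs2$pauli$values, gs$pauli$values)
  expect_identical(gs2$coulomb$values, gs$coulomb$values)
  expect_equal(gs2$meta$substrate_hash, gs$meta$substrate_hash)
  tmp2 <- tempfile(fileext = ".grid")
  write_field(fld, tmp2)
  f2 <- read_field(tmp2)
  expect_identical(f2$coulomb$coeffs, fld$coulomb$coeffs)
  expect_identical(f2$spec$dims, fld$spec$dims)
  # loader refuses the wrong representation
  expect_error(read_field(tmp), "B-spline")
  expect_error(read_gridset(tmp2), "node values")
  unlink(c(tmp, tmp2))
})
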