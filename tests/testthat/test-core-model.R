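# Pair laws, mixing, fixtures and the direct-sum / Ewald reference oracle.

test_that("Lorentz-Berthelot mixing combines depths and radii correctly", {
  m <- mix_lb(0.04, 1.5, 0.25, 2.5)
  expect_equal(m$eps, 0.1)
  expect_equal(m$R, 4.0)
  m2 <- mix_lb(0.07, 1.3, 0.07, 1.3)
  expect_equal(m2$eps, 0.07)
  expect_equal(m2$R, 2.6)
  m3 <- mix_lb(0, 1.0, 0.3, 2.0)
  expect_equal(m3$eps, 0)
  expect_equal(m3$R, 3.0)
  expect_error(mix_lb(-0.1, 1, 0.1, 1), "negative")
})

test_that("Morse pair law has its minimum at R and an analytic derivative", {
  out <- morse_pair(3.7, eps = 0.12, R = 3.7, alpha = 1.5)
  expect_equal(out$E, -0.12)
  expect_equal(out$dE_dr, 0, tolerance = 1e-14)
  # closed form at r = R + ln(2)/alpha: exp factor is exactly 1/2
  r <- 3.7 + log(2) / 1.5
  expect_equal(morse_pair(r, 0.12, 3.7, 1.5)$E, -0.75 * 0.12)
  # derivative vs central differences over random parameters
  set.seed(1)
  for (k in 1:20) {
    eps <- runif(1, 0.001, 0.3); R <- runif(1, 1, 4)
    a <- runif(1, 0.8, 2.5); r <- runif(1, 1.5, 8)
    h <- 1e-6
    fd <- (morse_pair(r + h, eps, R, a)$E - morse_pair(r - h, eps, R, a)$E) /
      (2 * h)
    an <- morse_pair(r, eps, R, a)$dE_dr
    expect_lt(abs(fd - an), 1e-8 * max(1, abs(an)))
  }
  expect_error(morse_pair(0, 0.1, 3, 1.5), "r must be")
})

test_that("factorized Morse sums reproduce the direct pair law exactly", {
  # algebraic identity of the factorization, no grids involved
  set.seed(7)
  sub <- random_substrate(12)
  pos <- cbind(runif(6, 0, 6), runif(6, 0, 6), runif(6, 2, 5))
  eps_i <- runif(6, 0.001, 0.1); R_i <- runif(6, 1.2, 2.2)
  spos <- as.matrix(sub$atoms[, c("x", "y", "z")])
  E_fact <- gridff:::cpp_factorized_morse(pos, eps_i, R_i, spos,
                                          sub$atoms$eps, sub$atoms$R, 1.5)
  for (i in 1:6) {
    r <- sqrt(rowSums(sweep(spos, 2, pos[i, ])^2))
    mix <- mix_lb(eps_i[i], R_i[i], sub$atoms$eps, sub$atoms$R)
    E_dir <- sum(mix$eps * (exp(-2 * 1.5 * (r - mix$R)) -
                            2 * exp(-1.5 * (r - mix$R))))
    expect_lt(abs(E_fact[i] - E_dir) / abs(E_dir), 1e-12)
  }
})

test_that("direct reference reduces to the pair law and saturates the cutoff", {
  at <- data.frame(element = "Na", x = 0, y = 0, z = 0, q = 0,
                   eps = 0.003, R = 1.5)
  sub <- substrate(at, diag(c(50, 50, 50)), periodic = c(TRUE, TRUE, FALSE))
  probe <- data.frame(element = "C", x = 0.4, y = 0.2, z = 3, q = 0,
                      eps = 0.0046, R = 1.93)
  mol <- molecule(probe)
  params <- global_params()
  out <- direct_reference(mol, sub, params, coulomb = "images")
  r <- sqrt(0.4^2 + 0.2^2 + 9)
  mix <- mix_lb(0.0046, 1.93, 0.003, 1.5)
  pair <- morse_pair(r, mix$eps, mix$R, params$alpha)
  expect_equal(out$E_morse, pair$E, tolerance = 1e-12)
  # force equals -dE/dr along the separation (Newton's third law partner)
  rhat <- c(0.4, 0.2, 3) / r
  expect_equal(as.numeric(out$F), -pair$dE_dr * rhat, tolerance = 1e-10)
  # cutoff saturation: more images change nothing
  out2 <- direct_reference(mol, sub, params, n_images = 4,
                           coulomb = "images")
  expect_identical(out$E_morse, out2$E_morse)
})

test_that("direct reference forces are exact gradients (random molecule over slab)", {
  sub <- build_rocksalt_slab(2, 2, 1)
  mol <- make_probe_molecule("flexible-chain", 5, seed = 9)
  pos <- as.matrix(mol$atoms[, c("x", "y", "z")])
  pos[, 3] <- pos[, 3] + 3.1 - min(pos[, 3])
  ew <- ewald_setup(sub, tol = 1e-10)
  out <- direct_reference(mol, sub, pos = pos, ewald = ew)
  fd <- num_grad(function(p) {
    o <- direct_reference(mol, sub, pos = p, ewald = ew)
    o$E_morse + o$E_coul
  }, pos, h = 1e-5)
  expect_lt(max(abs(out$F + fd)), 1e-6)
})

test_that("Ewald potential obeys charge antisymmetry and the isolated-pair limit", {
  sub <- unit_slab()
  # +- antisymmetry of the rocksalt surface: Na site vs Cl site
  V <- ewald_potential(sub, rbind(c(0, 0, 3), c(2, 2, 3)))
  expect_gt(V[1], 0)
  expect_equal(V[1], -V[2], tolerance = 1e-10)
  # mirror-plane point between the two sublattices
  V0 <- ewald_potential(sub, c(1, 1, 3))
  expect_lt(abs(V0), 1e-10)
  # two well-separated charges in a huge cell match k_e q / r
  at <- data.frame(element = c("Na", "Cl"), x = c(0, 8), y = 0, z = 0,
                   q = c(1, -1), eps = 0.001, R = 1.5)
  big <- substrate(at, diag(c(120, 120, 120)), rep(TRUE, 3))
  Vq <- ewald_potential(big, c(2, 0, 0), pad_above = 60, pad_below = 60)
  exact <- 14.399645 * (1 / 2 - 1 / 6)
  expect_lt(abs(Vq - exact) / exact, 1e-3)
  # non-neutral cell rejected
  at$q <- c(1, -0.5)
  expect_error(ewald_potential(substrate(at, diag(c(20, 20, 20))),
                               c(1, 1, 3)), "non-neutral")
})

test_that("Ewald potential is invariant under the splitting parameter", {
  sub <- unit_slab()
  pts <- rbind(c(0.3, 1.1, 2.8), c(2, 2, 4), c(1.7, 0.2, 3.5))
  V1 <- ewald_potential(sub, pts, beta = 0.7)
  V2 <- ewald_potential(sub, pts, beta = 1.0)
  V3 <- ewald_potential(sub, pts, beta = 1.4)
  expect_lt(max(abs(V1 - V2)), 1e-7)   # < 1e-4 meV
  expect_lt(max(abs(V2 - V3)), 1e-7)
})

test_that("rocksalt slab fixtures have the printed sizes and exact neutrality", {
  s <- build_rocksalt_slab(8, 8, 3)
  expect_identical(nrow(s$atoms), 384L)
  expect_identical(sum(s$atoms$q), 0)
  expect_identical(nrow(build_rocksalt_slab(20, 20, 3)$atoms), 2400L)
  s1 <- build_rocksalt_slab(1, 1, 1)
  expect_identical(nrow(s1$atoms), 2L)
  expect_setequal(s1$atoms$element, c("Na", "Cl"))
  expect_error(build_rocksalt_slab(2, 2, 2, qNa = 0.9, qCl = -0.8),
               "non-neutral")
})

test_that("vacancy pair removal keeps neutrality and hits the top layer", {
  s <- build_rocksalt_slab(6, 6, 3)
  ztop <- max(s$atoms$z)
  d <- introduce_vacancy_pair(s)
  expect_identical(nrow(d$atoms), nrow(s$atoms) - 2L)
  expect_identical(sum(d$atoms$q), 0)
  removed <- s$atoms[!do.call(paste, s$atoms[, c("x", "y", "z", "element")])
                     %in% do.call(paste, d$atoms[, c("x", "y", "z",
                                                     "element")]), ]
  expect_identical(nrow(removed), 2L)
  expect_true(all(removed$z == ztop))
  expect_setequal(removed$element, c("Na", "Cl"))
  # removed ions are nearest neighbours
  expect_equal(sqrt(sum((unlist(removed[1, c("x", "y", "z")]) -
                         unlist(removed[2, c("x", "y", "z")]))^2)),
               4 / sqrt(2), tolerance = 1e-9)
})

test_that("probe generator is deterministic, neutral and topologically consistent", {
  for (kind in c("rigid-planar", "flexible-chain", "polyol-chain")) {
    m1 <- make_probe_molecule(kind, 8, seed = 5)
    m2 <- make_probe_molecule(kind, 8, seed = 5)
    expect_identical(m1, m2)
    m3 <- make_probe_molecule(kind, 8, seed = 6)
    if (kind != "rigid-planar")           # planar ring carries no jitter
      expect_false(identical(m1$atoms, m3$atoms))
    expect_equal(sum(m1$atoms$q), 0, tolerance = 1e-14)
  }
  ch <- make_probe_molecule("flexible-chain", 8, seed = 1)
  expect_identical(nrow(ch$bonds), 7L)
  expect_identical(nrow(ch$angles), 6L)
  expect_identical(nrow(ch$torsions), 5L)
  expect_gte(nrow(make_probe_molecule("polyol-chain", 9, 1)$torsions), 1L)
  expect_error(make_probe_molecule("no-such-kind", 8, 1))
})
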