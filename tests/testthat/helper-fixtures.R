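# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# NaCl unit-cell substrate (1 x 1 x 3 layers, a = 4, q = +-0.9)
unit_slab <- function() cached("unit_slab", build_rocksalt_slab(1, 1, 3))

# fine (0.1 A) gridset + fitted field over the unit cell: the reference
# production pipeline, cheap enough to build once per run
unit_gridset <- function() cached("unit_gridset", {
  build_gridset(unit_slab(), surface_grid_spec(unit_slab()))
})

unit_field <- function() cached("unit_field", fit_gridset(unit_gridset()))

unit_direct <- function(tol = 1e-10) cached(paste0("unit_direct", tol), {
  direct_backend(unit_slab(), ewald_tol = tol)
})

# small random substrate (non-periodic) for brute-force oracles
random_substrate <- function(n = 10, seed = 4) {
  set.seed(seed)
  at <- data.frame(element = sample(c("Na", "Cl"), n, replace = TRUE),
                   x = runif(n, 0, 6), y = runif(n, 0, 6),
                   z = runif(n, -3, 0), q = 0, eps = runif(n, 0.001, 0.02),
                   R = runif(n, 1.2, 2.0), stringsAsFactors = FALSE)
  at$q <- rep(c(0.5, -0.5), length.out = n)
  if (n %% 2 == 1) at$q[n] <- 0
  substrate(at, diag(c(20, 20, 20)), periodic = c(FALSE, FALSE, FALSE))
}

# numeric gradient of a scalar function f(pos-matrix) -> scalar
num_grad <- function(f, pos, h = 1e-5) {
  g <- 0 * pos
  for (i in seq_len(nrow(pos))) {
    for (d in 1:3) {
      pp <- pos; pp[i, d] <- pp[i, d] + h
      pm <- pos; pm[i, d] <- pm[i, d] - h
      g[i, d] <- (f(pp) - f(pm)) / (2 * h)
    }
  }
  g
}
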