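# Replica minima hopping with RMSD-based uniqueness bookkeeping.

# RMSD between two equal-shape geometries, in the absolute surface frame
# (no superposition): translations by a lattice vector count as distinct
# adsorption sites.
rmsd_geoms <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("rmsd: mismatched atom counts")
  sqrt(mean(rowSums((a - b)^2)))
}

new_minima_set <- function(records = list(), counters = NULL,
                           threshold = 0.1) {
  structure(list(records = records,
                 counters = if (is.null(counters))
                   data.frame(cycle = integer(0), total = integer(0),
                              unique = integer(0)) else counters,
                 threshold = threshold),
            class = "gridff_minima")
}

#' @export
print.gridff_minima <- function(x, ...) {
  cat(sprintf("gridff minima set: %d unique records (RMSD threshold %g A)\n",
              length(x$records), x$threshold))
  if (nrow(x$counters))
    cat(sprintf("  after %d cycles: %d total relaxations\n",
                max(x$counters$cycle), max(x$counters$total)))
  invisible(x)
}

#' Greedy RMSD-based uniqueness filter
#'
#' First-seen canonicalization: a record is unique iff its RMSD (computed in
#' the absolute surface frame, without rotational/translational
#' superposition) to every already-accepted record exceeds the threshold.
#' Shifting a geometry by a full lattice vector therefore counts as a
#' distinct adsorption site.  With `fold_cell`, geometries are first folded
#' into the given lateral cell (opt-in symmetry reduction).
#'
#' @param records list of records, each with at least `$geometry`
#'   (n x 3 matrix); bare matrices are accepted too.
#' @param threshold RMSD threshold, Angstrom (default 0.1).
#' @param fold_cell optional 3x3 lattice to fold geometries into laterally
#'   before comparison.
#' @return a `gridff_minima` object with the unique records.
#' @export
rmsd_unique <- function(records, threshold = 0.1, fold_cell = NULL) {
  recs <- lapply(records, function(r)
    if (is.matrix(r)) list(geometry = r) else r)
  gkey <- lapply(recs, function(r) {
    g <- r$geometry
    if (!is.null(fold_cell)) {
      ctr <- colMeans(g)
      fc <- map_into_cell(ctr, fold_cell, c(TRUE, TRUE, FALSE))
      g <- sweep(g, 2, ctr - fc)
    }
    g
  })
  uni <- list(); ukey <- list()
  for (i in seq_along(recs)) {
    dup <- FALSE
    for (u in ukey) {
      if (rmsd_geoms(gkey[[i]], u) <= threshold) { dup <- TRUE; break }
    }
    if (!dup) {
      uni[[length(uni) + 1L]] <- recs[[i]]
      ukey[[length(ukey) + 1L]] <- gkey[[i]]
    }
  }
  new_minima_set(uni, threshold = threshold)
}

#' Replica minima hopping over the surface field
#'
#' Alternates thermal perturbation (Langevin MD at temperature `T`) with
#' FIRE relaxation to the nearest local minimum for every replica, collects
#' converged minima and maintains the unique set through the RMSD filter.
#' Replicas restart each cycle re-thermalized from their last relaxed
#' geometry.  Fully deterministic given the batch seeds; failed replicas
#' are excluded from the counts.
#'
#' @param batch a [make_replica_batch()].
#' @param cycles number of hop cycles.
#' @param T Langevin temperature, K (default 300).
#' @param n_md Langevin steps per cycle (default 1000).
#' @param gamma,dt Langevin friction (1/fs) and timestep (fs).
#' @param f_max relaxation force threshold, eV/Angstrom (default 1e-4,
#'   i.e. 0.1 meV/Angstrom).
#' @param threshold RMSD uniqueness threshold, Angstrom.
#' @param max_relax_steps FIRE step cap per relaxation.
#' @return a `gridff_minima` object; `$counters` tracks total and unique
#'   counts per cycle.
#' @export
minima_hop <- function(batch, cycles, T = 300, n_md = 1000, gamma = 0.01,
                       dt = 0.5, f_max = 1e-4, threshold = 0.1,
                       max_relax_steps = 20000) {
  system <- batch$system
  uni <- list(); ukey <- list()
  counters <- data.frame(cycle = integer(0), total = integer(0),
                         unique = integer(0))
  total <- 0L
  for (cyc in seq_len(cycles)) {
    batch <- run_langevin(batch, n_md, T = T, gamma = gamma, dt = dt)
    for (r in seq_len(batch$n)) {
      if (batch$failed[r]) next
      system$pos <- batch$pos[[r]]
      rr <- fire_relax(system, f_max = f_max, max_steps = max_relax_steps)
      if (!all(is.finite(rr$pos))) { batch$failed[r] <- TRUE; next }
      batch$pos[[r]] <- rr$pos         # re-thermalize from the minimum
      batch$vel[[r]] <- 0 * rr$pos
      if (!rr$converged) next
      total <- total + 1L
      rec <- list(geometry = rr$pos, energy = rr$energy$total,
                  replica = r, cycle = cyc, steps = rr$steps,
                  fmax = rr$fmax)
      dup <- FALSE
      for (u in ukey)
        if (rmsd_geoms(rr$pos, u) <= threshold) { dup <- TRUE; break }
      if (!dup) {
        uni[[length(uni) + 1L]] <- rec
        ukey[[length(ukey) + 1L]] <- rr$pos
      }
    }
    counters <- rbind(counters,
                      data.frame(cycle = cyc, total = total,
                                 unique = length(uni)))
  }
  out <- new_minima_set(uni, counters, threshold)
  attr(out, "batch") <- batch
  out
}
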