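# Experiment drivers: rigid vertical/lateral scans, relaxed pulling and
# dragging.  All drivers are backend-agnostic: the same protocol runs on the
# grid field or on the direct-sum reference.

make_scan_result <- function(coord, E_rows, converged, geometries = NULL,
                             extra = NULL) {
  df <- data.frame(coord = coord,
                   E_total = vapply(E_rows, function(e) e$total, 0),
                   E_bonded = vapply(E_rows, function(e) e$bonded, 0),
                   E_intra_nb = vapply(E_rows, function(e) e$intra_nb, 0),
                   E_surf_morse = vapply(E_rows, function(e) e$surf_morse, 0),
                   E_surf_coul = vapply(E_rows, function(e) e$surf_coul, 0),
                   converged = converged)
  if (!is.null(extra)) df <- cbind(df, extra)
  attr(df, "geometries") <- geometries
  class(df) <- c("gridff_scan", class(df))
  df
}

#' Rigid vertical scan
#'
#' Translates the molecule rigidly along z and records the energy
#' decomposition at each height.  The control coordinate is the height of
#' the molecule's reference point (by default its lowest atom) above z = 0,
#' which for the rocksalt fixtures is the top atomic layer.
#'
#' @param system an [mm_system()].
#' @param z_range `c(lo, hi)`, Angstrom.
#' @param step scan step, Angstrom.
#' @param ref_atom index of the reference atom; default = lowest atom.
#' @return a `gridff_scan` data.frame.
#' @export
rigid_z_scan <- function(system, z_range, step = 0.1, ref_atom = NULL) {
  stopifnot(length(z_range) == 2, z_range[2] > z_range[1], step > 0)
  base <- system$pos
  if (is.null(ref_atom)) ref_atom <- which.min(base[, 3])
  zs <- seq(z_range[1], z_range[2], by = step)
  E_rows <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    pos <- base
    pos[, 3] <- base[, 3] + (zs[i] - base[ref_atom, 3])
    E_rows[[i]] <- total_energy_force(system, pos)$E
  }
  make_scan_result(zs, E_rows, rep(TRUE, length(zs)))
}

#' Rigid lateral scan over one surface unit cell
#'
#' Translates the rigid molecule over the lateral cell at constant height
#' and maps the potential-energy surface.  Offsets cover `[0, L)` on both
#' lateral axes (periodic folding handles the boundary).
#'
#' @param system an [mm_system()].
#' @param height height of the molecule's reference point, Angstrom.
#' @param step lateral step, Angstrom.
#' @param cell optional 2x3 matrix of lateral cell vectors (default: the
#'   backend substrate/field cell).
#' @param ref_atom reference atom; default = lowest atom.
#' @return a `gridff_scan` data.frame with columns `x`, `y` (offsets).
#' @export
rigid_lateral_scan <- function(system, height = 3.3, step = 0.1,
                               cell = NULL, ref_atom = NULL) {
  base <- system$pos
  if (is.null(ref_atom)) ref_atom <- which.min(base[, 3])
  if (is.null(cell)) {
    cell <- if (system$backend$type == "grid")
      system$backend$field$spec$lattice[1:2, ]
    else system$backend$sub$lattice[1:2, ]
  }
  La <- sqrt(sum(cell[1, ]^2)); Lb <- sqrt(sum(cell[2, ]^2))
  ua <- seq(0, La - step / 2, by = step)
  ub <- seq(0, Lb - step / 2, by = step)
  offs <- expand.grid(x = ua, y = ub)
  shift0 <- c(base[ref_atom, 1:2], 0)
  E_rows <- vector("list", nrow(offs))
  ea <- cell[1, ] / La; eb <- cell[2, ] / Lb
  for (i in seq_len(nrow(offs))) {
    pos <- base
    off <- offs$x[i] * ea + offs$y[i] * eb - shift0
    pos[, 1] <- pos[, 1] + off[1]
    pos[, 2] <- pos[, 2] + off[2]
    pos[, 3] <- pos[, 3] + (height - base[ref_atom, 3])
    E_rows[[i]] <- total_energy_force(system, pos)$E
  }
  out <- make_scan_result(seq_len(nrow(offs)), E_rows,
                          rep(TRUE, nrow(offs)),
                          extra = data.frame(x = offs$x, y = offs$y))
  attr(out, "dims") <- c(length(ua), length(ub))
  out
}

#' Relaxed vertical pulling scan
#'
#' Restrains one anchor atom, displaces its z-coordinate step by step and
#' relaxes all other atoms with FIRE at every point, warm-started from the
#' previous relaxed geometry (cold start available for comparison).
#' Non-converged points are kept and flagged, not discarded.
#'
#' @param system an [mm_system()].
#' @param anchor index of the restrained atom.
#' @param z_start,z_end anchor heights, Angstrom.
#' @param step displacement per point, Angstrom.
#' @param f_max FIRE force threshold, eV/Angstrom.
#' @param max_steps FIRE step cap per point.
#' @param warm_start warm start each point from the previous geometry.
#' @param ... further arguments passed to [fire_relax()].
#' @return a `gridff_scan` data.frame with per-point geometries attached.
#' @export
relaxed_pull <- function(system, anchor, z_start, z_end, step = 0.1,
                         f_max = 1e-3, max_steps = 5000, warm_start = TRUE,
                         ...) {
  stopifnot(step > 0)
  system$constraints <- sort(unique(c(system$constraints, anchor)))
  zs <- seq(z_start, z_end, by = if (z_end >= z_start) step else -step)
  start_pos <- system$pos
  pos <- start_pos
  E_rows <- vector("list", length(zs))
  geoms <- vector("list", length(zs))
  conv <- logical(length(zs))
  for (i in seq_along(zs)) {
    if (!warm_start) pos <- start_pos
    pos[anchor, 3] <- zs[i]
    system$pos <- pos
    rr <- fire_relax(system, f_max = f_max, max_steps = max_steps, ...)
    pos <- rr$pos
    E_rows[[i]] <- rr$energy
    geoms[[i]] <- pos
    conv[i] <- rr$converged
  }
  make_scan_result(zs, E_rows, conv, geometries = geoms)
}

#' Relaxed lateral dragging scan
#'
#' Restrains one anchor atom and displaces it along a lateral direction in
#' fixed steps, relaxing the rest of the molecule at every point
#' (warm-started).  Besides the energy profile it records the lateral
#' trajectory of the anchor and of a free reference atom, whose deviation
#' from the anchor's straight path exposes stick-slip motion.
#'
#' @param system an [mm_system()].
#' @param anchor index of the restrained atom.
#' @param direction lateral direction (length-2), normalized internally.
#' @param length drag length, Angstrom.
#' @param step displacement per point, Angstrom.
#' @param f_max,max_steps FIRE controls.
#' @param ref_atom free reference atom; default = farthest from the anchor.
#' @param ... further arguments passed to [fire_relax()].
#' @return a `gridff_scan` data.frame with columns `anchor_x/y`,
#'   `ref_x/y` and geometries attached.
#' @export
drag_scan <- function(system, anchor, direction = c(1, 1), length,
                      step = 0.1, f_max = 1e-3, max_steps = 5000,
                      ref_atom = NULL, ...) {
  dirv <- direction / sqrt(sum(direction^2))
  system$constraints <- sort(unique(c(system$constraints, anchor)))
  pos <- system$pos
  if (is.null(ref_atom)) {
    d2 <- rowSums(sweep(pos[, 1:2, drop = FALSE], 2, pos[anchor, 1:2])^2)
    ref_atom <- which.max(d2)
  }
  p0 <- pos[anchor, 1:2]
  ss <- seq(0, length, by = step)
  E_rows <- vector("list", base::length(ss))
  geoms <- vector("list", base::length(ss))
  conv <- logical(base::length(ss))
  tr <- matrix(0, base::length(ss), 4)
  for (i in seq_along(ss)) {
    pos[anchor, 1:2] <- p0 + ss[i] * dirv
    system$pos <- pos
    rr <- fire_relax(system, f_max = f_max, max_steps = max_steps, ...)
    pos <- rr$pos
    E_rows[[i]] <- rr$energy
    geoms[[i]] <- pos
    conv[i] <- rr$converged
    tr[i, ] <- c(pos[anchor, 1:2], pos[ref_atom, 1:2])
  }
  make_scan_result(ss, E_rows, conv, geometries = geoms,
                   extra = data.frame(anchor_x = tr[, 1], anchor_y = tr[, 2],
                                      ref_x = tr[, 3], ref_y = tr[, 4]))
}
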