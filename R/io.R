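# File I/O: XYZ (standard + extended columns), MOL V2000, bond perception,
# grid containers and result writers.

#' Read an XYZ file
#'
#' Standard XYZ (count line, comment line, `element x y z` records) with
#' optional extended columns `charge eps R` honored when present.
#' Multi-frame files return a list of frames (order preserved).
#'
#' @param path file path.
#' @param multi if `TRUE`, always return a list of frames.
#' @return a data.frame (single frame) or list of data.frames; the comment
#'   line is attached as attribute `comment`.
#' @export
read_xyz <- function(path, multi = FALSE) {
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!grepl("\\S", lines[ln])) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1)
      stop("malformed XYZ count at line ", ln, " of ", path)
    if (ln + 1L + n > length(lines))
      stop("XYZ record count exceeds file length (count line ", ln, ")")
    comment <- lines[ln + 1L]
    recs <- lines[(ln + 2L):(ln + 1L + n)]
    parts <- strsplit(trimws(recs), "\\s+")
    ncol <- vapply(parts, length, 0L)
    if (any(ncol < 4))
      stop("malformed XYZ record at line ", ln + 1L + which(ncol < 4)[1],
           " of ", path)
    df <- suppressWarnings(data.frame(
      element = vapply(parts, `[`, "", 1),
      x = as.numeric(vapply(parts, `[`, "", 2)),
      y = as.numeric(vapply(parts, `[`, "", 3)),
      z = as.numeric(vapply(parts, `[`, "", 4)),
      stringsAsFactors = FALSE))
    if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z))
      stop("non-numeric coordinate in XYZ block starting at line ", ln)
    if (all(ncol >= 5)) df$q <- as.numeric(vapply(parts, `[`, "", 5))
    if (all(ncol >= 7)) {
      df$eps <- as.numeric(vapply(parts, `[`, "", 6))
      df$R <- as.numeric(vapply(parts, `[`, "", 7))
    }
    attr(df, "comment") <- comment
    frames[[length(frames) + 1L]] <- df
    ln <- ln + 2L + n
  }
  if (length(frames) == 0) stop("no frames in ", path)
  if (length(frames) == 1 && !multi) frames[[1]] else frames
}

#' Write an XYZ file
#'
#' @param x data.frame with `element, x, y, z` (optional `q`, `eps`, `R`
#'   written as extended columns), or a molecule/substrate, or a list of
#'   such frames (multi-frame output).
#' @param path file path.
#' @param comment per-frame comment line (recycled).
#' @param append append instead of overwrite.
#' @export
write_xyz <- function(x, path, comment = "", append = FALSE) {
  frames <- if (is.data.frame(x)) list(x)
            else if (inherits(x, c("gridff_molecule", "gridff_substrate")))
              list(x$atoms)
            else lapply(x, function(f)
              if (is.data.frame(f)) f else f$atoms)
  comment <- rep_len(comment, length(frames))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    df <- frames[[k]]
    ext <- all(c("q", "eps", "R") %in% names(df))
    lines <- c(sprintf("%d", nrow(df)), comment[k])
    for (i in seq_len(nrow(df))) {
      lines <- c(lines, if (ext)
        sprintf("%-2s %16.8f %16.8f %16.8f %12.6f %12.8f %12.6f",
                df$element[i], df$x[i], df$y[i], df$z[i], df$q[i],
                df$eps[i], df$R[i])
        else sprintf("%-2s %16.8f %16.8f %16.8f", df$element[i], df$x[i],
                     df$y[i], df$z[i]))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a MOL (V2000) file
#'
#' Minimal V2000 reader: counts line, atom block, bond block, and `M  CHG`
#' property charges when present.
#'
#' @param path file path.
#' @return list with `atoms` (data.frame `element x y z q`) and `bonds`
#'   (data.frame `i j order`).
#' @export
read_mol <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("malformed MOL file: ", path)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("malformed MOL counts line in ", path)
  at <- lines[5:(4 + na)]
  atoms <- data.frame(
    element = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    q = 0, stringsAsFactors = FALSE)
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    data.frame(i = as.integer(substr(bl, 1, 3)),
               j = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(i = integer(0), j = integer(0), order = integer(0))
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
    nch <- f[1]
    for (t in seq_len(nch))
      atoms$q[f[2 * t]] <- f[2 * t + 1]
  }
  list(atoms = atoms, bonds = bonds)
}

#' Detect bonding topology from geometry
#'
#' Two atoms are bonded iff their distance is below
#' `scale * (r_cov_i + r_cov_j)` (covalent radii).
#'
#' @param structure data.frame with `element, x, y, z` (or molecule /
#'   substrate).
#' @param scale distance scale factor (default 1.2).
#' @return data.frame of bonds `i, j`.
#' @export
detect_bonds <- function(structure, scale = 1.2) {
  df <- if (is.data.frame(structure)) structure else structure$atoms
  rc <- .covalent_radii[df$element]
  if (anyNA(rc))
    stop("no covalent radius for element(s): ",
         paste(unique(df$element[is.na(rc)]), collapse = ", "))
  p <- as.matrix(df[, c("x", "y", "z")])
  n <- nrow(p)
  out <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((p[i, ] - p[j, ])^2))
      if (d < scale * (rc[i] + rc[j]))
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (length(out)) {
    m <- do.call(rbind, out)
    data.frame(i = m[, 1], j = m[, 2])
  } else data.frame(i = integer(0), j = integer(0))
}

# ---- grid containers -------------------------------------------------------
# One file per grid set: a single JSON header line followed by raw
# little-endian float64 arrays (z-fastest C order) for each component.

.write_container <- function(path, header, arrays) {
  header$dtype <- "float64"
  header$endian <- "little"
  header$arrays <- names(arrays)
  header$n_values <- length(arrays[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  hj <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  writeBin(charToRaw(paste0(as.character(hj), "\n")), con)
  for (a in arrays) writeBin(as.numeric(a), con, size = 8, endian = "little")
  invisible(path)
}

.read_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_head <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop("truncated container header: ", path)
    if (b == charToRaw("\n")) break
    raw_head <- c(raw_head, b)
  }
  header <- jsonlite::fromJSON(rawToChar(raw_head))
  if (!identical(header$dtype, "float64") ||
      !identical(header$endian, "little"))
    stop("unsupported container payload in ", path)
  nv <- header$n_values
  arrays <- list()
  for (nm in header$arrays) {
    v <- readBin(con, "numeric", nv, size = 8, endian = "little")
    if (length(v) != nv) stop("truncated payload (", nm, ") in ", path)
    arrays[[nm]] <- v
  }
  list(header = header, arrays = arrays)
}

spec_to_header <- function(spec) {
  list(origin = spec$origin, spacing = spec$spacing, dims = spec$dims,
       lattice = as.numeric(spec$lattice), periodic = spec$periodic)
}

spec_from_header <- function(h) {
  grid_spec(h$origin, h$spacing, h$dims, matrix(h$lattice, 3, 3),
            h$periodic)
}

#' Write / read a grid set container
#'
#' Single-file container: JSON header (grid spec, alpha, cutoff, substrate
#' hash, dtype/endianness) followed by the three raw float64 arrays.
#'
#' @param gridset a `gridff_gridset`.
#' @param path file path.
#' @return `path` (write) / the grid set (read).
#' @export
write_gridset <- function(gridset, path) {
  header <- c(list(representation = "node-values",
                   alpha = gridset$alpha),
              gridset$meta[c("substrate_hash", "r_cut", "sigma")],
              spec_to_header(gridset$pauli$spec))
  .write_container(path, header,
                   list(pauli = gridset$pauli$values,
                        london = gridset$london$values,
                        coulomb = gridset$coulomb$values))
}

#' @rdname write_gridset
#' @export
read_gridset <- function(path) {
  ct <- .read_container(path)
  h <- ct$header
  if (!identical(h$representation, "node-values"))
    stop("container does not hold node values: ", path)
  spec <- spec_from_header(h)
  structure(list(pauli = scalar_field(spec, ct$arrays$pauli, "sqrt(eV)"),
                 london = scalar_field(spec, ct$arrays$london, "sqrt(eV)"),
                 coulomb = scalar_field(spec, ct$arrays$coulomb, "eV/e"),
                 alpha = h$alpha,
                 meta = list(substrate_hash = h$substrate_hash,
                             r_cut = h$r_cut, sigma = h$sigma,
                             spacing = h$spacing)),
            class = "gridff_gridset")
}

#' Write / read a fitted B-spline field container
#'
#' Same container format as [write_gridset()] with a
#' `representation: bspline-coeffs` header flag.
#'
#' @param field a `gridff_field` from [fit_gridset()].
#' @param path file path.
#' @export
write_field <- function(field, path) {
  header <- c(list(representation = "bspline-coeffs", alpha = field$alpha),
              field$meta[c("substrate_hash", "r_cut", "sigma")],
              spec_to_header(field$spec))
  .write_container(path, header,
                   list(pauli = field$pauli$coeffs,
                        london = field$london$coeffs,
                        coulomb = field$coulomb$coeffs))
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  ct <- .read_container(path)
  h <- ct$header
  if (!identical(h$representation, "bspline-coeffs"))
    stop("container does not hold B-spline coefficients: ", path)
  spec <- spec_from_header(h)
  mk <- function(v, unit) {
    structure(list(coeffs = v, spec = spec,
                   boundary = ifelse(spec$periodic, "periodic", "clamped"),
                   fit_report = list(method = "loaded", iterations = NA,
                                     rms = NA),
                   unit = unit), class = "gridff_bspline")
  }
  structure(list(pauli = mk(ct$arrays$pauli, "sqrt(eV)"),
                 london = mk(ct$arrays$london, "sqrt(eV)"),
                 coulomb = mk(ct$arrays$coulomb, "eV/e"),
                 spec = spec, alpha = h$alpha,
                 meta = list(substrate_hash = h$substrate_hash,
                             r_cut = h$r_cut, sigma = h$sigma)),
            class = "gridff_field")
}

#' Write a scan result as tab-separated text
#'
#' Columns: control coordinate, energy decomposition, convergence flag; a
#' provenance comment carries the grid container hash when available.
#'
#' @param scan a `gridff_scan`.
#' @param path output path.
#' @param xyz_path optional multi-frame XYZ of the per-point geometries.
#' @param provenance optional named list written into the header comment.
#' @export
write_scan <- function(scan, path, xyz_path = NULL, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", paste(names(provenance), unlist(provenance),
                                  sep = "=", collapse = " ")), con)
  df <- as.data.frame(scan)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  if (!is.null(xyz_path) && !is.null(attr(scan, "geometries"))) {
    geoms <- attr(scan, "geometries")
    frames <- lapply(seq_along(geoms), function(i) {
      data.frame(element = rep("X", nrow(geoms[[i]])),
                 x = geoms[[i]][, 1], y = geoms[[i]][, 2],
                 z = geoms[[i]][, 3])
    })
    write_xyz(frames, xyz_path,
              comment = sprintf("point %d coord %.4f E_total %.8f",
                                seq_along(geoms), df$coord,
                                df$E_total))
  }
  invisible(path)
}

#' Write a minima set (XYZ concatenation + JSON index)
#'
#' @param minima a `gridff_minima`.
#' @param xyz_path multi-frame XYZ of the unique geometries.
#' @param json_path JSON index (energy, replica, cycle per record).
#' @param elements element symbols for the XYZ records.
#' @export
write_minima <- function(minima, xyz_path, json_path, elements = NULL) {
  recs <- minima$records
  frames <- lapply(recs, function(r) {
    g <- r$geometry
    data.frame(element = if (is.null(elements)) rep("X", nrow(g))
               else elements, x = g[, 1], y = g[, 2], z = g[, 3])
  })
  write_xyz(frames, xyz_path,
            comment = vapply(recs, function(r)
              sprintf("E %.8f replica %d cycle %d", r$energy, r$replica,
                      r$cycle), ""))
  idx <- lapply(recs, function(r)
    list(energy = r$energy, replica = r$replica, cycle = r$cycle,
         steps = r$steps))
  jsonlite::write_json(list(threshold = minima$threshold,
                            counters = minima$counters, records = idx),
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(xyz_path)
}
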