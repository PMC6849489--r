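#' Molecular geometry
#'
#' Container for a molecular structure: element labels, Cartesian coordinates
#' (stored in Bohr) and per-atom masses (atomic mass units). Masses default to
#' standard atomic weights looked up from the element labels.
#'
#' @param atoms Character vector of element symbols, length N (N >= 2).
#' @param coords Numeric N x 3 matrix of Cartesian positions in Bohr.
#' @param masses Optional numeric vector of per-atom masses in amu; looked up
#'   from `atoms` when omitted.
#' @return An object of class `"geometry"` with fields `atoms`, `coords`
#'   (Bohr) and `masses` (amu).
#' @export
#' @examples
#' g <- geometry(c("O", "H", "H"),
#'               matrix(c(0, 0, 0, 1.8, 0, 0, -0.45, 1.75, 0), 3, 3, byrow = TRUE))
#' flatten_coords(g)
geometry <- function(atoms, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (length(atoms) < 2L) stop("geometry needs at least two atoms")
  if (nrow(coords) != length(atoms) || ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix matching length(atoms)")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(masses)) {
    unknown <- setdiff(atoms, names(.atomic_masses))
    if (length(unknown) > 0)
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    masses <- unname(.atomic_masses[atoms])
  }
  if (length(masses) != length(atoms) || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and finite, one per atom")
  structure(list(atoms = atoms, coords = coords, masses = masses),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d atoms (%s), coordinates in Bohr\n",
              length(x$atoms), paste(x$atoms, collapse = " ")))
  invisible(x)
}

#' Flatten / rebuild geometry coordinates
#'
#' `flatten_coords()` returns the coordinates of a geometry as a flat numeric
#' vector in the order x1, y1, z1, x2, ... (Bohr) -- the layout used by all
#' providers and by the dynamics driver. `unflatten_coords()` writes such a
#' vector back into a geometry.
#'
#' @param geom A `geometry`.
#' @param x Flat numeric coordinate vector of length 3N (Bohr).
#' @return A numeric vector, or a `geometry` for `unflatten_coords()`.
#' @export
flatten_coords <- function(geom) as.vector(t(geom$coords))

#' @rdname flatten_coords
#' @export
unflatten_coords <- function(geom, x) {
  stopifnot(length(x) == 3L * length(geom$atoms))
  geom$coords <- matrix(x, ncol = 3L, byrow = TRUE)
  geom
}

# Per-degree-of-freedom masses in atomic units (electron masses) for a
# Cartesian geometry: each atomic mass repeated for x, y, z.
dof_masses_au <- function(geom) rep(geom$masses * .me_per_amu, each = 3L)

#' Read and write XYZ geometry files
#'
#' Standard (multi-frame) XYZ format with coordinates in Angstrom. Parsing
#' errors report the offending line number; unknown element symbols and
#' malformed atom-count lines are rejected.
#'
#' @param path File path.
#' @param geoms A `geometry` or list of geometries (for writing).
#' @param comments Optional character vector of per-frame comment lines.
#' @param digits Number of digits printed per coordinate.
#' @return `read_xyz()` returns a list of `geometry` objects (coordinates
#'   converted to Bohr); `write_xyz()` returns `path` invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty XYZ file: ", path)
  geoms <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1)
      stop(sprintf("malformed atom-count line %d in %s: '%s'", ln, path, lines[ln]))
    if (ln + 1L + nat > length(lines))
      stop(sprintf("truncated frame starting at line %d in %s", ln, path))
    atoms <- character(nat)
    xyz <- matrix(NA_real_, nat, 3)
    for (a in seq_len(nat)) {
      fields <- strsplit(trimws(lines[ln + 1L + a]), "\\s+")[[1]]
      if (length(fields) < 4)
        stop(sprintf("malformed coordinate line %d in %s", ln + 1L + a, path))
      atoms[a] <- fields[1]
      vals <- suppressWarnings(as.numeric(fields[2:4]))
      if (any(is.na(vals)))
        stop(sprintf("non-numeric coordinates on line %d in %s", ln + 1L + a, path))
      xyz[a, ] <- vals
    }
    unknown <- setdiff(atoms, names(.atomic_masses))
    if (length(unknown) > 0)
      stop(sprintf("unknown element '%s' in frame starting at line %d of %s",
                   unknown[1], ln, path))
    geoms[[length(geoms) + 1L]] <- geometry(atoms, xyz * .bohr_per_ang)
    ln <- ln + 2L + nat
  }
  geoms
}

#' @rdname read_xyz
#' @export
write_xyz <- function(geoms, path, comments = NULL, digits = 10) {
  if (inherits(geoms, "geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(geoms)) {
    g <- geoms[[f]]
    writeLines(as.character(length(g$atoms)), con)
    writeLines(if (is.null(comments)) sprintf("frame %d", f) else comments[[f]], con)
    xyz <- g$coords * .ang_per_bohr
    fmt <- paste0("%-3s ", paste(rep(sprintf("%%.%df", digits), 3), collapse = " "))
    for (a in seq_along(g$atoms))
      writeLines(sprintf(fmt, g$atoms[a], xyz[a, 1], xyz[a, 2], xyz[a, 3]), con)
  }
  invisible(path)
}

#' Build a triatomic geometry from its three interatomic distances
#'
#' Places atom 1 at the origin, atom 2 on the x axis and atom 3 in the
#' xy plane. Used to construct configurations of the bundled triatomic
#' conical-intersection model from internal coordinates.
#'
#' @param r12,r13,r23 Interatomic distances in Bohr; must satisfy the triangle
#'   inequality.
#' @param atoms Element labels (default three carbons, matching the bundled
#'   model).
#' @return A `geometry`.
#' @export
triatomic_geometry <- function(r12, r13, r23, atoms = c("C", "C", "C")) {
  if (r12 + r13 <= r23 || r12 + r23 <= r13 || r13 + r23 <= r12)
    stop("distances violate the triangle inequality")
  x3 <- (r12^2 + r13^2 - r23^2) / (2 * r12)
  y3 <- sqrt(max(r13^2 - x3^2, 0))
  geometry(atoms, rbind(c(0, 0, 0), c(r12, 0, 0), c(x3, y3, 0)))
}

#' Interatomic distances of a flat coordinate vector
#'
#' @param x Flat Cartesian coordinates (Bohr), length 3N.
#' @return Numeric vector of pairwise distances in the lexicographic pair
#'   order (1,2), (1,3), ..., (N-1,N).
#' @export
internal_distances <- function(x) {
  xm <- matrix(x, ncol = 3, byrow = TRUE)
  n <- nrow(xm)
  pr <- state_pairs(n)  # same lexicographic (a < b) layout
  vapply(seq_len(nrow(pr)), function(p) {
    sqrt(sum((xm[pr[p, 1], ] - xm[pr[p, 2], ])^2))
  }, numeric(1))
}
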