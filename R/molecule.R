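# Molecular geometries as tibbles: one row per atom, columns element, x, y, z
# (Angstrom) and type (force-field-style atom-type label, NA until assigned).

#' Construct a molecule
#'
#' A molecule is a tibble with one row per atom and columns `element`, `x`,
#' `y`, `z` (Cartesian coordinates in Angstrom) and `type` (atom-type label,
#' `NA` until [assign_types()] or [set_atom_types()] is applied).
#'
#' @param element Character vector of element symbols.
#' @param coords Numeric matrix with one row per atom and three columns, in
#'   Angstrom.
#' @param type Optional character vector of atom-type labels.
#' @param name Free-text molecule name stored as an attribute.
#' @return A tibble of class `fgc_molecule`.
#' @examples
#' molecule("H", matrix(c(0, 0, 0), 1), type = "HX")
#' @export
molecule <- function(element, coords, type = NA_character_, name = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(element) != nrow(coords)) {
    abort("`element` and `coords` disagree on the number of atoms.")
  }
  if (!all(is.finite(coords))) {
    abort("all coordinates must be finite")
  }
  mol <- tibble::tibble(
    element = as.character(element),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    type = rep_len(as.character(type), length(element))
  )
  attr(mol, "name") <- name
  class(mol) <- c("fgc_molecule", class(mol))
  mol
}

#' @export
print.fgc_molecule <- function(x, ...) {
  nm <- attr(x, "name")
  if (!is.null(nm) && nzchar(nm)) cat("# Molecule:", nm, "\n")
  NextMethod()
}

coords_matrix <- function(mol) {
  as.matrix(mol[, c("x", "y", "z")])
}

#' Set atom types directly
#'
#' Convenience for synthetic systems where the labels are known rather than
#' derived from bonding rules.
#'
#' @param mol A molecule.
#' @param types Character vector, one label per atom.
#' @return The molecule with its `type` column replaced.
#' @export
set_atom_types <- function(mol, types) {
  if (length(types) != nrow(mol)) {
    abort("`types` must supply one label per atom")
  }
  mol$type <- as.character(types)
  mol
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ format: an atom-count line, a comment line, then one
#' `element x y z` row per atom (coordinates in Angstrom).
#'
#' @param path Path to an XYZ file.
#' @return A molecule; atom types are `NA` until typing is applied.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort(sprintf("'%s': not an XYZ file (fewer than 2 lines)", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    abort(sprintf("'%s' line 1: malformed atom-count line '%s'", path, lines[1]))
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    abort(sprintf("'%s': count line says %d atoms but only %d atom rows found",
                  path, n, length(body)))
  }
  fields <- strsplit(trimws(body[seq_len(n)]), "[[:space:]]+")
  elem <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 4) abort(sprintf("'%s' atom line %d: expected 'element x y z'", path, i + 2))
    elem[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(v)) abort(sprintf("'%s' atom line %d: non-numeric coordinate", path, i + 2))
    xyz[i, ] <- v
  }
  molecule(elem, xyz, name = trimws(lines[2]))
}

#' Write a molecule to an XYZ file
#'
#' @param mol A molecule.
#' @param path Output path.
#' @param digits Decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_xyz_frame(mol, digits), con)
  invisible(path)
}

format_xyz_frame <- function(mol, digits = 6, comment = NULL) {
  comment <- comment %||% attr(mol, "name") %||% ""
  fmt <- sprintf("%%-3s %%.%df %%.%df %%.%df", digits, digits, digits)
  c(as.character(nrow(mol)), comment,
    sprintf(fmt, mol$element, mol$x, mol$y, mol$z))
}

# Covalent radii (Angstrom, Cordero et al. consensus values) for the elements
# the built-in typing rules can meet.
covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

#' Infer covalent connectivity
#'
#' Two atoms are bonded when their distance is below 1.2 times the sum of
#' their covalent radii — the standard deterministic heuristic.
#'
#' @param mol A molecule.
#' @param scale Multiplier on the covalent-radius sum.
#' @return A logical adjacency matrix.
#' @export
connectivity <- function(mol, scale = 1.2) {
  r <- covalent_radii[mol$element]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    abort(sprintf("no covalent radius for element '%s' (atom %d)", mol$element[bad], bad))
  }
  xyz <- coords_matrix(mol)
  d <- as.matrix(stats::dist(xyz))
  cut <- scale * outer(r, r, `+`)
  adj <- d < cut & d > 0
  diag(adj) <- FALSE
  adj
}
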