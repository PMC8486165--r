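# Rigid-body intermolecular potential energy curve (IPEC) scans. An
# orientation fixes the pose of both monomers and designates one "attack"
# atom in each; the scan coordinate r is the attack-atom separation, realised
# by translating molecule B along the approach axis with both internal
# geometries frozen.

rotation_about <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(theta); s <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c + ux^2 * (1 - c),      ux * uy * (1 - c) - uz * s, ux * uz * (1 - c) + uy * s,
    uy * ux * (1 - c) + uz * s, c + uy^2 * (1 - c),      uy * uz * (1 - c) - ux * s,
    uz * ux * (1 - c) - uy * s, uz * uy * (1 - c) + ux * s, c + uz^2 * (1 - c)
  ), 3, 3, byrow = TRUE)
}

# Rotation taking unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- perp - sum(perp * u) * u
    return(rotation_about(ax, pi))
  }
  rotation_about(c(u[2] * v[3] - u[3] * v[2],
                   u[3] * v[1] - u[1] * v[3],
                   u[1] * v[2] - u[2] * v[1]), acos(d))
}

transform_mol <- function(mol, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- coords_matrix(mol) %*% t(R)
  mol$x <- xyz[, 1] + shift[1]
  mol$y <- xyz[, 2] + shift[2]
  mol$z <- xyz[, 3] + shift[3]
  mol
}

#' Build a dimer orientation from attack atoms
#'
#' Poses molecule A with its attack atom at the origin and the rest of the
#' molecule swung onto the -z side, and molecule B (stored relative to its
#' attack atom) facing it from the +z side; [build_scan()] then places B's
#' attack atom at `r` times the approach axis. Azimuthal angles rotate each
#' monomer about the approach axis to vary the flanking contacts.
#'
#' @param mol_a,mol_b Molecules (typed or not).
#' @param attack_a,attack_b Attack-atom indices.
#' @param azimuth_a,azimuth_b Rotations about the approach axis, radians.
#' @param id Orientation label.
#' @return An object of class `fgc_orientation`.
#' @export
build_orientation <- function(mol_a, mol_b, attack_a, attack_b,
                              azimuth_a = 0, azimuth_b = 0, id = "orientation") {
  stopifnot(attack_a >= 1, attack_a <= nrow(mol_a),
            attack_b >= 1, attack_b <= nrow(mol_b))
  axis <- c(0, 0, 1)
  pose <- function(mol, attack, facing, azimuth) {
    xyz <- coords_matrix(mol)
    cen <- colMeans(xyz)
    dir <- xyz[attack, ] - cen
    R <- if (sqrt(sum(dir^2)) < 1e-9) diag(3) else rotation_between(dir, facing)
    R <- rotation_about(axis, azimuth) %*% R
    mol <- transform_mol(mol, R)
    transform_mol(mol, diag(3), -coords_matrix(mol)[attack, ])
  }
  structure(list(
    mol_a = pose(mol_a, attack_a, c(0, 0, 1), azimuth_a),
    mol_b = pose(mol_b, attack_b, c(0, 0, -1), azimuth_b),
    attack_a = as.integer(attack_a), attack_b = as.integer(attack_b),
    axis = axis, id = as.character(id),
    azimuth_a = azimuth_a, azimuth_b = azimuth_b
  ), class = "fgc_orientation")
}

#' @export
print.fgc_orientation <- function(x, ...) {
  cat(sprintf("<fgc_orientation '%s'> attack %s[%d] ... %s[%d] along (%g, %g, %g)\n",
              x$id, x$mol_a$type[x$attack_a] %||% "?", x$attack_a,
              x$mol_b$type[x$attack_b] %||% "?", x$attack_b,
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Generate the rigid scan geometries of an orientation
#'
#' Molecule A stays fixed; molecule B is rigidly translated so that its
#' attack atom sits exactly at `r` times the approach axis from A's attack
#' atom. Internal geometries are bitwise frozen.
#'
#' @param orient An `fgc_orientation`.
#' @param r_grid Strictly increasing attack-atom separations, Angstrom.
#' @return A list with one element per grid point, each
#'   `list(mol_a, mol_b, r)`.
#' @export
build_scan <- function(orient, r_grid) {
  if (any(r_grid <= 0) || any(diff(r_grid) <= 0)) {
    abort("r_grid must be strictly increasing and positive")
  }
  anchor_a <- coords_matrix(orient$mol_a)[orient$attack_a, ]
  anchor_b <- coords_matrix(orient$mol_b)[orient$attack_b, ]
  lapply(r_grid, function(r) {
    shift <- anchor_a + r * orient$axis - anchor_b
    list(mol_a = orient$mol_a,
         mol_b = transform_mol(orient$mol_b, diag(3), shift),
         r = r)
  })
}

#' Correction energy along a scan
#'
#' @param orient An `fgc_orientation` whose monomers are typed.
#' @param r_grid Strictly increasing separations, Angstrom.
#' @param params An `fgc_params` parameter set.
#' @return An energy-curve tibble (class `fgc_curves`) with columns
#'   `orientation_id`, `r`, `energy`, `energy_kind = "correction"`.
#' @export
correction_curve <- function(orient, r_grid, params) {
  frames <- build_scan(orient, r_grid)
  energy_curve(orient$id, r_grid,
               vapply(frames, function(f) dimer_correction(f$mol_a, f$mol_b, params),
                      numeric(1)),
               "correction")
}

#' Energy-curve tibble
#'
#' @param orientation_id Orientation label(s).
#' @param r Strictly increasing distances per orientation, Angstrom.
#' @param energy Energies, kJ/mol (finite).
#' @param energy_kind One of `"reference"`, `"sqm"`, `"difference"`,
#'   `"correction"`, `"corrected"`.
#' @return A tibble of class `fgc_curves`.
#' @export
energy_curve <- function(orientation_id, r, energy,
                         energy_kind = c("reference", "sqm", "difference",
                                         "correction", "corrected")) {
  energy_kind <- match.arg(energy_kind)
  if (length(r) != length(energy)) abort("r and energy must have equal length")
  if (!all(is.finite(energy))) abort("energies must be finite")
  cv <- tibble::tibble(orientation_id = rep_len(orientation_id, length(r)),
                       r = as.numeric(r), energy = as.numeric(energy),
                       energy_kind = energy_kind)
  class(cv) <- c("fgc_curves", class(cv))
  cv
}

#' Drop high-energy points from a curve
#'
#' Retains points with `energy <= e_max`, preserving order — the standard
#' repulsive-wall cap applied before fitting (typical caps run from about 23
#' to 141 kJ/mol depending on orientation).
#'
#' @param curve An energy-curve tibble.
#' @param e_max Cap in kJ/mol.
#' @return The filtered curve; warns (does not error) when nothing survives.
#' @export
apply_energy_filter <- function(curve, e_max) {
  if (!is.finite(e_max) && e_max != Inf) abort("e_max must be finite or +Inf")
  out <- dplyr::filter(curve, .data$energy <= e_max)
  if (!nrow(out)) warn("energy filter removed every point; returning an empty curve")
  out
}

#' Read / write energy-curve CSV files
#'
#' Columns: `orientation_id`, `r` (Angstrom), `energy` (kJ/mol),
#' `energy_kind`.
#'
#' @param path CSV path.
#' @return `read_curves()` returns an `fgc_curves` tibble.
#' @export
read_curves <- function(path) {
  # parse numerics from text with strtod for correctly rounded round-trips
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  df$r <- as.numeric(df$r)
  df$energy <- as.numeric(df$energy)
  cv <- tibble::as_tibble(df[, c("orientation_id", "r", "energy", "energy_kind")])
  class(cv) <- c("fgc_curves", class(cv))
  cv
}

#' @rdname read_curves
#' @param curves An `fgc_curves` tibble.
#' @export
write_curves <- function(curves, path) {
  out <- curves[, c("orientation_id", "r", "energy", "energy_kind")]
  # %.17g guarantees the decimal strings re-parse to bit-identical doubles
  out$r <- sprintf("%.17g", out$r)
  out$energy <- sprintf("%.17g", out$energy)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a scan as a concatenated-frame XYZ trajectory
#'
#' @param frames Output of [build_scan()].
#' @param path Output path.
#' @param digits Decimal places for coordinates.
#' @export
write_scan_xyz <- function(frames, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    dim_mol <- molecule(c(f$mol_a$element, f$mol_b$element),
                        rbind(coords_matrix(f$mol_a), coords_matrix(f$mol_b)))
    writeLines(format_xyz_frame(dim_mol, digits,
                                comment = sprintf("r = %.6f", f$r)), con)
  }
  invisible(path)
}
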