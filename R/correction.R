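# The pairwise correction energy. For one intermolecular atom pair at
# distance r the correction is
#
#   E(r) = f_cut(r) * ( A * exp(-B * r) + C / r^n )
#
# with the sigmoid damping f_cut(r) = 1 / (1 + exp(-s * (r - d))), which is
# exactly 1/2 at r = d, vanishes at short range and tends to 1 at long range.
# The dimer correction is the sum of E over all intermolecular pairs, each
# pair drawing its parameters from its pair type.

#' Short-range cutoff function
#'
#' `1 / (1 + exp(-s * (r - d)))`: strictly increasing in `r`, exactly 1/2 at
#' `r = d`, approaching 0 as `r -> 0` and 1 as `r -> Inf`. The exponent is
#' clamped to +/-500 (beyond which the value is 0/1 to double precision).
#'
#' @param r Distance(s), Angstrom (non-negative).
#' @param s Steepness (positive).
#' @param d Midpoint distance, Angstrom.
#' @return Values in (0, 1), vectorised over `r`.
#' @export
f_cut <- function(r, s, d) {
  if (any(r < 0)) abort("r must be non-negative")
  z <- pmin(pmax(-s * (r - d), -500), 500)
  1 / (1 + exp(z))
}

#' Single-pair correction energy
#'
#' @param r Distance(s) in Angstrom, strictly positive.
#' @param A,B,C,n,s,d Pair parameters (see [parameter_set()]).
#' @return Correction energy in kJ/mol, vectorised over `r`.
#' @export
pair_energy <- function(r, A, B, C, n, s = 10, d = 1) {
  if (any(r <= 0)) abort("r must be strictly positive")
  f_cut(r, s, d) * (A * exp(-B * r) + C / r^n)
}

# dE/dr for the pair correction: f' g + f g' with f' = s f (1 - f).
pair_denergy <- function(r, A, B, C, n, s = 10, d = 1) {
  f <- f_cut(r, s, d)
  g <- A * exp(-B * r) + C / r^n
  gp <- -A * B * exp(-B * r) - n * C / r^(n + 1)
  s * f * (1 - f) * g + f * gp
}

# Long tables of intermolecular pairs: one row per (i in A, j in B) with the
# distance, unit vector and parameter row.
intermolecular_pairs <- function(mol_a, mol_b, params) {
  if (anyNA(mol_a$type) || anyNA(mol_b$type)) {
    abort("both molecules must be typed before evaluating the correction")
  }
  na <- nrow(mol_a); nb <- nrow(mol_b)
  i <- rep(seq_len(na), times = nb)
  j <- rep(seq_len(nb), each = na)
  dx <- mol_b$x[j] - mol_a$x[i]
  dy <- mol_b$y[j] - mol_a$y[i]
  dz <- mol_b$z[j] - mol_a$z[i]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  keys <- pair_key(mol_a$type[i], mol_b$type[j])
  list(i = i, j = j, r = r, dx = dx, dy = dy, dz = dz,
       row = param_rows(params, keys), key = keys)
}

#' Dimer correction energy
#'
#' Sum of [pair_energy()] over all intermolecular atom pairs (no
#' intramolecular pairs contribute). Symmetric under swapping the two
#' molecules. Every occurring pair type must be present in `params`.
#'
#' @param mol_a,mol_b Typed molecules.
#' @param params An `fgc_params` parameter set.
#' @return Correction energy in kJ/mol.
#' @export
dimer_correction <- function(mol_a, mol_b, params) {
  p <- intermolecular_pairs(mol_a, mol_b, params)
  sum(pair_energy(p$r, params$A[p$row], params$B[p$row], params$C[p$row],
                  params$n[p$row], params$s[p$row], params$d[p$row]))
}

#' Per-pair-type decomposition of the dimer correction
#'
#' @inheritParams dimer_correction
#' @return A tibble with columns `key`, `n_pairs`, `energy` (kJ/mol); the
#'   energies sum to [dimer_correction()].
#' @export
pair_decomposition <- function(mol_a, mol_b, params) {
  p <- intermolecular_pairs(mol_a, mol_b, params)
  e <- pair_energy(p$r, params$A[p$row], params$B[p$row], params$C[p$row],
                   params$n[p$row], params$s[p$row], params$d[p$row])
  tibble::tibble(key = p$key, energy = e) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_pairs = dplyr::n(), energy = sum(.data$energy),
                     .groups = "drop") |>
    dplyr::arrange(.data$key)
}

#' Analytic Cartesian gradient of the dimer correction
#'
#' @inheritParams dimer_correction
#' @return A tibble with columns `mol` (`"a"`/`"b"`), `atom`, `gx`, `gy`,
#'   `gz` in kJ mol^-1 Angstrom^-1. The atomic gradients sum to the zero
#'   vector (translation invariance).
#' @export
dimer_gradient <- function(mol_a, mol_b, params) {
  p <- intermolecular_pairs(mol_a, mol_b, params)
  dEdr <- pair_denergy(p$r, params$A[p$row], params$B[p$row], params$C[p$row],
                       params$n[p$row], params$s[p$row], params$d[p$row])
  w <- dEdr / p$r
  ga <- cbind(
    gx = -rowsum_vec(w * p$dx, p$i, nrow(mol_a)),
    gy = -rowsum_vec(w * p$dy, p$i, nrow(mol_a)),
    gz = -rowsum_vec(w * p$dz, p$i, nrow(mol_a))
  )
  gb <- cbind(
    gx = rowsum_vec(w * p$dx, p$j, nrow(mol_b)),
    gy = rowsum_vec(w * p$dy, p$j, nrow(mol_b)),
    gz = rowsum_vec(w * p$dz, p$j, nrow(mol_b))
  )
  tibble::tibble(
    mol = rep(c("a", "b"), c(nrow(mol_a), nrow(mol_b))),
    atom = c(seq_len(nrow(mol_a)), seq_len(nrow(mol_b))),
    gx = unname(c(ga[, "gx"], gb[, "gx"])),
    gy = unname(c(ga[, "gy"], gb[, "gy"])),
    gz = unname(c(ga[, "gz"], gb[, "gz"]))
  )
}

rowsum_vec <- function(v, idx, n) {
  out <- numeric(n)
  acc <- rowsum(v, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Corrected interaction energy
#'
#' Adds the pairwise correction to an externally computed SQM interaction
#' energy for the same dimer geometry.
#'
#' @param e_sqm SQM interaction energy, kJ/mol.
#' @inheritParams dimer_correction
#' @return `e_sqm + dimer_correction(mol_a, mol_b, params)` in kJ/mol.
#' @export
corrected_interaction_energy <- function(e_sqm, mol_a, mol_b, params) {
  e_sqm + dimer_correction(mol_a, mol_b, params)
}
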