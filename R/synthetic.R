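# Synthetic study systems with known ground truth. The generator emulates
# the ingredients of an IPEC fitting campaign without any electronic
# structure: a smooth Morse-like mock "SQM" baseline per orientation, a
# ground-truth pairwise correction, optional Gaussian noise, and a
# repulsive-energy cap (drawn per orientation from the 23-141 kJ/mol range
# typical of curated fit sets).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Idealized monomer geometries
#'
#' Hard-coded idealized geometries (Angstrom, three decimals) for the three
#' built-in functional-group representatives. Untyped; apply
#' [assign_types()].
#'
#' @param name One of `"methane"`, `"formic_acid"`, `"ammonia"`.
#' @return A molecule.
#' @export
template_molecule <- function(name = c("methane", "formic_acid", "ammonia")) {
  name <- match.arg(name)
  switch(name,
    methane = molecule(
      c("C", "H", "H", "H", "H"),
      rbind(c(0, 0, 0),
            c(0.629, 0.629, 0.629), c(-0.629, -0.629, 0.629),
            c(-0.629, 0.629, -0.629), c(0.629, -0.629, -0.629)),
      name = "methane"),
    ammonia = molecule(
      c("N", "H", "H", "H"),
      rbind(c(0, 0, 0), c(0, 0.943, -0.383),
            c(0.817, -0.472, -0.383), c(-0.817, -0.472, -0.383)),
      name = "ammonia"),
    formic_acid = molecule(
      c("C", "O", "O", "H", "H"),
      rbind(c(0, 0, 0), c(1.202, 0, 0), c(-0.768, 1.101, 0),
            c(-0.610, -0.912, 0), c(-0.159, 1.858, 0)),
      name = "formic_acid")
  )
}

#' Specification of a synthetic fitting study
#'
#' @param mol_a,mol_b Typed monomers.
#' @param truth Ground-truth `fgc_params` covering every pair type of the
#'   system.
#' @param same_species Is the system a homodimer of one species?
#' @param noise_sd Gaussian noise on the energy differences, kJ/mol.
#' @param r_window Attack-atom separation window, Angstrom.
#' @param grid_step Grid spacing, Angstrom.
#' @param e_max_range Range the per-orientation repulsive cap is drawn from,
#'   kJ/mol.
#' @param base Ranges for the Morse-like mock SQM baseline: well depth `de`
#'   (kJ/mol), range `a` (1/Angstrom), minimum position `re` (Angstrom).
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A list of class `fgc_synthetic_spec`.
#' @export
synthetic_spec <- function(mol_a, mol_b, truth, same_species = TRUE,
                           noise_sd = 0, r_window = c(2.5, 6), grid_step = 0.1,
                           e_max_range = c(23, 141),
                           base = list(de = c(2, 15), a = c(1.5, 2.5),
                                       re = c(3.2, 4.2)),
                           seed = 1) {
  if (anyNA(mol_a$type) || anyNA(mol_b$type)) abort("monomers must be typed")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (length(r_window) != 2 || r_window[1] <= 0 || diff(r_window) <= 0) {
    abort("r_window must be a positive increasing range")
  }
  structure(list(mol_a = mol_a, mol_b = mol_b, truth = truth,
                 same_species = same_species, noise_sd = noise_sd,
                 r_window = r_window, grid_step = grid_step,
                 e_max_range = e_max_range, base = base,
                 seed = as.integer(seed)),
            class = "fgc_synthetic_spec")
}

#' Draw a random ground-truth parameter set
#'
#' Amplitudes span the magnitude range typical of fitted functional-group
#' corrections: `|A|` up to about 3e5 kJ/mol, `|C|` up to about 3e3, `B` in
#' 2-5.5 1/Angstrom and integer `n` between 2 and 11.
#'
#' @param cutoffs Tibble `type_a`, `type_b`, `s`, `d` listing the pair types.
#' @param seed Integer seed.
#' @return An `fgc_params` set.
#' @export
random_truth <- function(cutoffs, seed = 1) {
  K <- nrow(cutoffs)
  with_seed(seed, {
    parameter_set(cutoffs$type_a, cutoffs$type_b,
                  A = runif(K, -3e5, 3e5), B = runif(K, 2, 5.5),
                  C = runif(K, -3e3, 3e3), n = sample(2:11, K, replace = TRUE),
                  s = cutoffs$s, d = cutoffs$d,
                  provenance = sprintf("random truth (seed %d)", seed))
  })
}

#' Generate orientations covering every pair type
#'
#' Builds `n_orient` rigid orientations whose attack-atom pairs jointly
#' cover every pair type of the system — mirroring the rule that a fitting
#' campaign needs at least as many orientations as pair types. Deterministic
#' for a fixed spec seed.
#'
#' @param spec An `fgc_synthetic_spec`.
#' @param n_orient Number of orientations; must be at least the number of
#'   pair types.
#' @return A list of `fgc_orientation` objects.
#' @export
make_orientations <- function(spec, n_orient) {
  pairs <- enumerate_pair_types(unique(spec$mol_a$type), unique(spec$mol_b$type),
                                same_species = spec$same_species)
  K <- nrow(pairs)
  if (n_orient < K) {
    abort(sprintf(paste0(
      "n_orient = %d is below the %d pair types of this system; ",
      "coverage requires at least as many orientations as pair types"),
      n_orient, K))
  }
  with_seed(spec$seed, {
    lapply(seq_len(n_orient), function(k) {
      pr <- pairs[(k - 1L) %% K + 1L, ]
      ia <- which(spec$mol_a$type == pr$type_a)
      ib <- which(spec$mol_b$type == pr$type_b)
      if (!length(ia) || !length(ib)) {
        ia <- which(spec$mol_a$type == pr$type_b)
        ib <- which(spec$mol_b$type == pr$type_a)
      }
      build_orientation(spec$mol_a, spec$mol_b,
                        attack_a = ia[1], attack_b = ib[1],
                        azimuth_a = runif(1, 0, 2 * pi),
                        azimuth_b = runif(1, 0, 2 * pi),
                        id = sprintf("o%02d_%s", k, pr$key))
    })
  })
}

# One deterministic pass per orientation: Morse baseline parameters, the
# repulsive cap, truth correction and the noise draw. Shared by the
# difference-curve and reference/SQM generators so they agree exactly.
synth_points <- function(spec, orientations) {
  r_grid <- seq(spec$r_window[1], spec$r_window[2], by = spec$grid_step)
  rows <- lapply(seq_along(orientations), function(k) {
    or <- orientations[[k]]
    frames <- build_scan(or, r_grid)
    corr <- vapply(frames, function(f) dimer_correction(f$mol_a, f$mol_b, spec$truth),
                   numeric(1))
    with_seed(spec$seed + k, {
      de <- runif(1, spec$base$de[1], spec$base$de[2])
      a <- runif(1, spec$base$a[1], spec$base$a[2])
      re <- runif(1, spec$base$re[1], spec$base$re[2])
      e_max <- runif(1, spec$e_max_range[1], spec$e_max_range[2])
      noise <- rnorm(length(r_grid), 0, spec$noise_sd)
      base <- de * ((1 - exp(-a * (r_grid - re)))^2 - 1)
      tibble::tibble(orientation_id = or$id, r = r_grid, base = base,
                     corr = corr, noise = noise, e_max = e_max,
                     mol_a = lapply(frames, `[[`, "mol_a"),
                     mol_b = lapply(frames, `[[`, "mol_b"))
    })
  })
  pts <- dplyr::bind_rows(rows)
  pts$reference <- pts$base + pts$corr + pts$noise
  pts[pts$reference <= pts$e_max, ]
}

#' Generate reference-minus-SQM difference data with known truth
#'
#' For every orientation and retained grid point,
#' `y = dimer_correction(truth) + N(0, noise_sd)`; with `noise_sd = 0` the
#' dataset is exactly representable by the model, so a perfect fit attains
#' chi2 = 0. Points whose mock reference energy exceeds the orientation's
#' repulsive cap are dropped.
#'
#' @param spec An `fgc_synthetic_spec`.
#' @param orientations Output of [make_orientations()].
#' @return An `fgc_fitdata` tibble with unit weights.
#' @export
make_difference_curves <- function(spec, orientations) {
  pts <- synth_points(spec, orientations)
  out <- tibble::tibble(orientation_id = pts$orientation_id, r = pts$r,
                        y = pts$corr + pts$noise, w = 1,
                        mol_a = pts$mol_a, mol_b = pts$mol_b)
  class(out) <- c("fgc_fitdata", class(out))
  out
}

#' Generate matched mock reference and SQM curves
#'
#' The SQM curve is the Morse-like baseline; the reference curve adds the
#' ground-truth correction and the same noise draw as
#' [make_difference_curves()], so `reference - sqm` reproduces that dataset
#' exactly for matching seeds.
#'
#' @inheritParams make_difference_curves
#' @return A list with `fgc_curves` elements `reference` and `sqm`.
#' @export
make_reference_and_sqm <- function(spec, orientations) {
  pts <- synth_points(spec, orientations)
  list(
    reference = energy_curve(pts$orientation_id, pts$r, pts$reference, "reference"),
    sqm = energy_curve(pts$orientation_id, pts$r, pts$base, "sqm")
  )
}
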