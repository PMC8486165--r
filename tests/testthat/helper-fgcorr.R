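# Shared fixtures and independent oracles. The oracles here are written as
# plain scalar loops, independent of the package's vectorized paths.

# Naive O(N^2) double-loop evaluation of the dimer correction, scalar
# arithmetic only.
loop_correction <- function(mol_a, mol_b, params) {
  total <- 0
  for (i in seq_len(nrow(mol_a))) {
    for (j in seq_len(nrow(mol_b))) {
      r <- sqrt((mol_a$x[i] - mol_b$x[j])^2 + (mol_a$y[i] - mol_b$y[j])^2 +
                (mol_a$z[i] - mol_b$z[j])^2)
      ta <- mol_a$type[i]; tb <- mol_b$type[j]
      key <- paste(min(ta, tb), max(ta, tb), sep = ":")
      row <- which(params$key == key)
      stopifnot(length(row) == 1)
      fc <- 1 / (1 + exp(-params$s[row] * (r - params$d[row])))
      total <- total + fc * (params$A[row] * exp(-params$B[row] * r) +
                             params$C[row] / r^params$n[row])
    }
  }
  total
}

# A random typed dimer drawing labels from the formic acid type set, with a
# minimum interatomic separation so inverse powers stay finite.
random_typed_dimer <- function(n_a = 4, n_b = 4, min_sep = 1.2) {
  labels <- c("C", "O", "OH", "HO", "HCO")
  elements <- c(C = "C", O = "O", OH = "O", HO = "H", HCO = "H")
  repeat {
    ta <- sample(labels, n_a, replace = TRUE)
    tb <- sample(labels, n_b, replace = TRUE)
    xa <- matrix(runif(3 * n_a, -1.5, 1.5), ncol = 3)
    xb <- matrix(runif(3 * n_b, -1.5, 1.5), ncol = 3)
    xb[, 3] <- xb[, 3] + 4.5
    d <- sqrt(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb))
    if (min(d) > min_sep) break
  }
  list(
    mol_a = set_atom_types(molecule(elements[ta], xa), ta),
    mol_b = set_atom_types(molecule(elements[tb], xb), tb)
  )
}

# Two-pair-type synthetic study: an X2 diatomic against an XY diatomic.
two_type_system <- function(seed = 42, noise_sd = 0) {
  ma <- set_atom_types(molecule(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.1))), c("X", "X"))
  mb <- set_atom_types(molecule(c("N", "O"), rbind(c(0, 0, 0), c(0, 0, 1.2))), c("X", "Y"))
  pairs <- enumerate_pair_types(unique(ma$type), unique(mb$type), same_species = FALSE)
  cutoffs <- default_cutoffs(pairs, c(X = "N", Y = "O"))
  truth <- parameter_set(pairs$type_a, pairs$type_b,
                         A = c(2e5, -8e4), B = c(3.5, 4.2),
                         C = c(-1500, 600), n = c(6L, 4L),
                         s = 10, d = cutoffs$d, provenance = "synthetic truth")
  spec <- synthetic_spec(ma, mb, truth, same_species = FALSE,
                         noise_sd = noise_sd, seed = seed)
  list(mol_a = ma, mol_b = mb, pairs = pairs, cutoffs = cutoffs,
       truth = truth, spec = spec)
}

# Formic-acid-like homodimer study with the packaged parameters as truth.
formic_system <- function(seed = 11, grid_step = 0.2) {
  fa <- assign_types(template_molecule("formic_acid"))
  truth <- formic_acid_dimer_params()
  spec <- synthetic_spec(fa, fa, truth, same_species = TRUE,
                         r_window = c(2.6, 6), grid_step = grid_step,
                         seed = seed)
  list(mol = fa, truth = truth, spec = spec)
}
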