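fa_params <- formic_acid_dimer_params()

test_that("cutoff anchors at 1/2, is monotone and has the right limits", {
  for (k in seq_len(nrow(fa_params))) {
    expect_identical(f_cut(fa_params$d[k], fa_params$s[k], fa_params$d[k]), 0.5)
  }
  expect_equal(f_cut(1e6, 10, 1), 1)
  # independent scalar evaluation of the sigmoid at r = 0, s = 10, d = 1
  expect_lt(f_cut(0, 10, 1), 1e-4)
  expect_equal(f_cut(0, 10, 1), 1 / (1 + exp(10)), tolerance = 1e-12)
  # monotone non-decreasing everywhere; strictly increasing wherever the
  # sigmoid is still resolvable in double precision
  r <- seq(0, 8, by = 0.01)
  for (k in seq_len(nrow(fa_params))) {
    v <- f_cut(r, fa_params$s[k], fa_params$d[k])
    expect_true(all(diff(v) >= 0))
    near <- r <= fa_params$d[k] + 2
    expect_true(all(diff(v[near]) > 0))
  }
  expect_error(f_cut(-0.1, 10, 1), "non-negative")
})

test_that("pair energy matches an independent scalar evaluation and decays", {
  # HO-HO row at r = 2: f * (A exp(-2B) + C/4), evaluated step by step
  f <- 1 / (1 + exp(-10 * (2 - 1)))
  expected <- f * (2029.79 * exp(-3.07 * 2) + 27.04 / 2^2)
  expect_equal(pair_energy(2, 2029.79, 3.07, 27.04, 2, 10, 1.0),
               expected, tolerance = 1e-12)
  expect_equal(pair_energy(c(1, 3, 7), 0, 2, 0, 6), c(0, 0, 0))
  # decay: every packaged pair type is negligible by 1e4 Angstrom
  for (k in seq_len(nrow(fa_params))) {
    expect_lt(abs(pair_energy(1e4, fa_params$A[k], fa_params$B[k], fa_params$C[k],
                              fa_params$n[k], fa_params$s[k], fa_params$d[k])), 1e-6)
  }
  expect_error(pair_energy(0, 1, 1, 1, 6), "positive")
})

test_that("dimer correction reduces to pair energy for single-atom monomers", {
  pa <- set_atom_types(molecule("H", matrix(c(0, 0, 0), 1)), "HO")
  pb <- set_atom_types(molecule("H", matrix(c(0, 0, 2.3), 1)), "HO")
  k <- which(fa_params$key == "HO:HO")
  expect_equal(dimer_correction(pa, pb, fa_params),
               pair_energy(2.3, fa_params$A[k], fa_params$B[k], fa_params$C[k],
                           fa_params$n[k], fa_params$s[k], fa_params$d[k]))
})

test_that("vectorized correction equals the double-loop oracle on random dimers", {
  set.seed(101)
  for (rep in 1:50) {
    dm <- random_typed_dimer()
    expect_equal(dimer_correction(dm$mol_a, dm$mol_b, fa_params),
                 loop_correction(dm$mol_a, dm$mol_b, fa_params),
                 tolerance = 1e-9)
  }
})

test_that("correction is swap-symmetric and rigid-motion invariant", {
  set.seed(7)
  dm <- random_typed_dimer()
  e0 <- dimer_correction(dm$mol_a, dm$mol_b, fa_params)
  expect_identical(e0, dimer_correction(dm$mol_b, dm$mol_a, fa_params))
  # common rotation + translation of both monomers
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  move <- function(m) {
    xyz <- as.matrix(m[, c("x", "y", "z")]) %*% R
    m$x <- xyz[, 1] + 3.2; m$y <- xyz[, 2] - 1.1; m$z <- xyz[, 3] + 0.4
    m
  }
  expect_equal(dimer_correction(move(dm$mol_a), move(dm$mol_b), fa_params), e0,
               tolerance = 1e-9)
})

test_that("missing pair parameters raise a named lookup error", {
  pa <- set_atom_types(molecule("H", matrix(c(0, 0, 0), 1)), "HO")
  pz <- set_atom_types(molecule("H", matrix(c(0, 0, 2), 1)), "ZZ")
  expect_error(dimer_correction(pa, pz, fa_params), "HO:ZZ")
  expect_error(dimer_correction(pa, pz, fa_params), "no parameters")
})

test_that("analytic gradient matches central finite differences", {
  # every packaged pair type as an isolated atom pair
  for (k in seq_len(nrow(fa_params))) {
    ta <- fa_params$type_a[k]; tb <- fa_params$type_b[k]
    elements <- c(C = "C", O = "O", OH = "O", HO = "H", HCO = "H")
    pa <- set_atom_types(molecule(elements[ta], matrix(c(0, 0, 0), 1)), ta)
    pb <- set_atom_types(molecule(elements[tb], matrix(c(0.4, -0.3, 2.1), 1)), tb)
    g <- dimer_gradient(pa, pb, fa_params)
    h <- 1e-5
    for (dim in c("x", "y", "z")) {
      shift <- function(m, s) { m[[dim]] <- m[[dim]] + s; m }
      num <- (dimer_correction(pa, shift(pb, h), fa_params) -
              dimer_correction(pa, shift(pb, -h), fa_params)) / (2 * h)
      expect_equal(g[[paste0("g", dim)]][g$mol == "b"], num, tolerance = 1e-6)
    }
  }
  # a full random dimer, all atoms, all components
  set.seed(13)
  dm <- random_typed_dimer()
  g <- dimer_gradient(dm$mol_a, dm$mol_b, fa_params)
  h <- 1e-5
  for (side in c("a", "b")) {
    m <- if (side == "a") dm$mol_a else dm$mol_b
    for (atom in seq_len(nrow(m))) {
      for (dim in c("x", "y", "z")) {
        mp <- m; mp[[dim]][atom] <- mp[[dim]][atom] + h
        mm <- m; mm[[dim]][atom] <- mm[[dim]][atom] - h
        num <- if (side == "a") {
          (dimer_correction(mp, dm$mol_b, fa_params) -
           dimer_correction(mm, dm$mol_b, fa_params)) / (2 * h)
        } else {
          (dimer_correction(dm$mol_a, mp, fa_params) -
           dimer_correction(dm$mol_a, mm, fa_params)) / (2 * h)
        }
        got <- g[[paste0("g", dim)]][g$mol == side][atom]
        expect_equal(got, num, tolerance = 1e-6)
      }
    }
  }
  # translation invariance: atomic gradients sum to zero
  expect_equal(colSums(as.matrix(g[, c("gx", "gy", "gz")])), c(gx = 0, gy = 0, gz = 0),
               tolerance = 1e-9)
})

test_that("gradient reduces to (-dE/dr, 0, 0) for a pair on the x axis", {
  pa <- set_atom_types(molecule("O", matrix(c(0, 0, 0), 1)), "O")
  pb <- set_atom_types(molecule("O", matrix(c(2.8, 0, 0), 1)), "O")
  g <- dimer_gradient(pa, pb, fa_params)
  h <- 1e-6
  k <- which(fa_params$key == "O:O")
  dEdr <- (pair_energy(2.8 + h, fa_params$A[k], fa_params$B[k], fa_params$C[k],
                       fa_params$n[k], fa_params$s[k], fa_params$d[k]) -
           pair_energy(2.8 - h, fa_params$A[k], fa_params$B[k], fa_params$C[k],
                       fa_params$n[k], fa_params$s[k], fa_params$d[k])) / (2 * h)
  expect_equal(g$gx[1], -dEdr, tolerance = 1e-5)
  expect_equal(c(g$gy[1], g$gz[1]), c(0, 0))
})

test_that("corrected interaction energy is additive and zero corrections pass through", {
  set.seed(19)
  dm <- random_typed_dimer()
  corr <- loop_correction(dm$mol_a, dm$mol_b, fa_params)
  expect_equal(corrected_interaction_energy(-10, dm$mol_a, dm$mol_b, fa_params),
               -10 + corr, tolerance = 1e-9)
  expect_equal(corrected_interaction_energy(0, dm$mol_a, dm$mol_b, fa_params), corr)
  zero <- parameter_set(fa_params$type_a, fa_params$type_b, A = 0, B = 1, C = 0,
                        n = fa_params$n, s = fa_params$s, d = fa_params$d)
  expect_equal(corrected_interaction_energy(-7.5, dm$mol_a, dm$mol_b, zero), -7.5)
})

test_that("per-pair decomposition sums to the total", {
  set.seed(23)
  dm <- random_typed_dimer()
  dec <- pair_decomposition(dm$mol_a, dm$mol_b, fa_params)
  expect_equal(sum(dec$energy), dimer_correction(dm$mol_a, dm$mol_b, fa_params),
               tolerance = 1e-9)
  expect_equal(sum(dec$n_pairs), nrow(dm$mol_a) * nrow(dm$mol_b))
})
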