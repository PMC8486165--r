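# Single-atom monomers at three separations make chi2 hand-checkable.
hand_dataset <- function(y = c(2, -1, 0.5), w = c(1, 2, 3)) {
  pa <- set_atom_types(molecule("O", matrix(c(0, 0, 0), 1)), "O")
  pb <- set_atom_types(molecule("O", matrix(c(0, 0, 1), 1)), "O")
  or <- build_orientation(pa, pb, 1, 1, id = "pp")
  fit_dataset(list(or), energy_curve("pp", c(2.5, 3, 3.5), y, "difference"), w = w)
}

test_that("chi2 matches hand arithmetic against the zero model", {
  ds <- hand_dataset()
  zero <- parameter_set("O", "O", A = 0, B = 1, C = 0, n = 6, s = 10, d = 1.7)
  expect_equal(chi2(ds, zero), 1 * 2^2 + 2 * (-1)^2 + 3 * 0.5^2)
  # all-zero weights give zero objective
  expect_equal(chi2(hand_dataset(w = 0), zero), 0)
})

test_that("chi2 is zero at the generating truth and linear in the weights", {
  sys <- two_type_system(seed = 42)
  ors <- make_orientations(sys$spec, 6)
  ds <- make_difference_curves(sys$spec, ors)
  expect_lt(chi2(ds, sys$truth), 1e-12)
  other <- parameter_set(sys$pairs$type_a, sys$pairs$type_b,
                         A = c(1e4, 2e4), B = c(3, 3), C = c(100, -100),
                         n = c(6L, 6L), s = 10, d = sys$cutoffs$d)
  ds2 <- ds
  ds2$w <- 2 * ds2$w
  expect_equal(chi2(ds2, other), 2 * chi2(ds, other), tolerance = 1e-12)
})

test_that("GA fit recovers noiseless truth curves and reports consistently", {
  sys <- two_type_system(seed = 42)
  ors <- make_orientations(sys$spec, 7)
  ds <- make_difference_curves(sys$spec, ors)
  expect_gte(nrow(ds), 200)
  cfg <- fit_config(seed = 7, pop_size = 100, generations = 120)
  fit <- fit_parameters(ds, cfg)
  # curve recovery: RMSE of the fitted model against the truth differences
  rmse <- sqrt(mean(fit$residuals^2))
  expect_lt(rmse, 0.5)
  # elitist monotonicity of the best-so-far objective
  expect_true(all(diff(fit$chi2_history) <= 0))
  # the reported objective equals an independent re-evaluation
  expect_equal(chi2(ds, fit$params), fit$chi2, tolerance = 1e-9 * max(1, fit$chi2))
  expect_equal(sum(ds$w * fit$residuals^2), fit$chi2, tolerance = 1e-9)
  # integer exponents stay within bounds
  expect_true(all(fit$params$n >= 1 & fit$params$n <= 12))
  # broom-style accessors
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(glance(fit)$n_parameters, 8)
})

test_that("the same seed reproduces a fit bit-exactly", {
  sys <- two_type_system(seed = 42)
  ors <- make_orientations(sys$spec, 6)
  ds <- make_difference_curves(sys$spec, ors)
  cfg <- fit_config(seed = 3, pop_size = 40, generations = 25)
  f1 <- fit_parameters(ds, cfg)
  f2 <- fit_parameters(ds, cfg)
  expect_identical(f1$params$A, f2$params$A)
  expect_identical(f1$params$n, f2$params$n)
  expect_identical(f1$chi2_history, f2$chi2_history)
})

test_that("a null signal yields a near-zero fitted correction", {
  sys <- two_type_system(seed = 42)
  ors <- make_orientations(sys$spec, 6)
  ds <- make_difference_curves(sys$spec, ors)
  ds$y <- 0 * ds$y
  fit <- fit_parameters(ds, fit_config(seed = 5, pop_size = 60, generations = 40))
  expect_lt(max(abs(fit$fitted)), 0.1)
})

test_that("config validation rejects degenerate setups", {
  expect_error(fit_config(), "seed")
  expect_error(fit_config(seed = 1, bounds = list(A = c(1, -1), B = c(0.5, 8),
                                                  C = c(-1, 1), n = c(1, 12))),
               "bounds")
  expect_error(fit_config(seed = 1, pop_size = 1), "pop_size")
  sys <- two_type_system()
  ors <- make_orientations(sys$spec, 6)
  expect_error(fit_dataset(ors, energy_curve("nope", 2, 1, "difference")),
               "unknown orientation")
})

test_that("type merging relabels geometries and expansion warm-starts exactly", {
  sys <- two_type_system(seed = 42)
  ors <- make_orientations(sys$spec, 6)
  ds <- make_difference_curves(sys$spec, ors)
  merged <- merge_types(ds, c(Y = "X"))
  pt <- unique(unlist(lapply(merged$mol_b, function(m) m$type)))
  expect_equal(pt, "X")
  # expansion: every fine pair inherits its coarse parameters
  coarse <- parameter_set("X", "X", A = 123, B = 2.5, C = -45, n = 7,
                          s = 10, d = 1.7)
  fine <- expand_params(coarse, sys$cutoffs, c(Y = "X"))
  expect_equal(fine$A, c(123, 123))
  expect_equal(fine$n, c(7L, 7L))
  # the expanded genome scores on the fine problem exactly as the coarse
  # genome scores on the merged problem
  expect_equal(chi2(ds, fine), chi2(merged, coarse), tolerance = 1e-9)
})
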