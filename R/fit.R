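# Simultaneous least-squares fitting of all pair-type parameters to
# reference-minus-SQM energy differences. The objective is
#
#   chi2(a) = sum_i w_i * (y_i - f(x_i; a))^2
#
# where x_i is a dimer geometry, y_i the energy difference at that geometry
# and f the pairwise correction. The search is an elitist generational
# genetic algorithm over the concatenated (A, B, C real; n integer) genome,
# optionally followed by a Levenberg-Marquardt polish of the real parameters
# at fixed n. The cutoff constants (s, d) are fixed per pair type, never
# fitted.

#' Assemble a fit dataset
#'
#' One row per data point: the scan geometry, the target energy difference
#' `y` (kJ/mol) and its weight `w`.
#'
#' @param orientations List of `fgc_orientation` objects.
#' @param curves An `fgc_curves` tibble of `energy_kind = "difference"`
#'   points, matched to orientations by `orientation_id`.
#' @param w Weights (recycled; default unity, the usual choice).
#' @return A tibble of class `fgc_fitdata` with columns `orientation_id`,
#'   `r`, `y`, `w`, `mol_a`, `mol_b` (list columns of typed molecules).
#' @export
fit_dataset <- function(orientations, curves, w = 1) {
  ids <- vapply(orientations, `[[`, "", "id")
  unknown <- setdiff(unique(curves$orientation_id), ids)
  if (length(unknown)) {
    abort(sprintf("curves reference unknown orientation(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  curves$..w <- rep_len(as.numeric(w), nrow(curves))
  rows <- lapply(orientations, function(or) {
    pts <- curves[curves$orientation_id == or$id, ]
    if (!nrow(pts)) return(NULL)
    pts <- pts[order(pts$r), ]
    frames <- build_scan(or, pts$r)
    tibble::tibble(orientation_id = or$id, r = pts$r, y = pts$energy,
                   w = pts$..w,
                   mol_a = lapply(frames, `[[`, "mol_a"),
                   mol_b = lapply(frames, `[[`, "mol_b"))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) abort("fit dataset is empty")
  if (any(out$w < 0)) abort("weights must be non-negative")
  class(out) <- c("fgc_fitdata", class(out))
  out
}

# Distinct pair types occurring in a dataset, with the element each label sits
# on (needed for default cutoff assignment).
dataset_pair_types <- function(dataset) {
  labs <- list(); elems <- character()
  for (k in seq_len(nrow(dataset))) {
    for (m in list(dataset$mol_a[[k]], dataset$mol_b[[k]])) {
      elems[m$type] <- m$element
    }
  }
  types_a <- unique(unlist(lapply(dataset$mol_a, function(m) unique(m$type))))
  types_b <- unique(unlist(lapply(dataset$mol_b, function(m) unique(m$type))))
  g <- expand.grid(a = types_a, b = types_b, stringsAsFactors = FALSE)
  pk <- tibble::tibble(type_a = pmin(g$a, g$b), type_b = pmax(g$a, g$b),
                       key = pair_key(g$a, g$b))
  pk <- dplyr::distinct(dplyr::arrange(pk, .data$key))
  list(pairs = pk, elements = elems)
}

#' Default cutoff constants for a set of pair types
#'
#' Steepness `s = 10` throughout; midpoint `d` by atom-pair class: 1.0 A for
#' H-H pairs, 1.2 A for heavy-H, 1.7 A for heavy-heavy and 1.8 A for C-C.
#'
#' @param pairs Tibble with `type_a`, `type_b`, `key`.
#' @param elements Named character vector mapping type labels to element
#'   symbols.
#' @return `pairs` with `s` and `d` columns appended.
#' @export
default_cutoffs <- function(pairs, elements) {
  ea <- elements[pairs$type_a]; eb <- elements[pairs$type_b]
  d <- ifelse(ea == "H" & eb == "H", 1.0,
       ifelse(ea == "H" | eb == "H", 1.2,
       ifelse(ea == "C" & eb == "C", 1.8, 1.7)))
  dplyr::mutate(pairs, s = 10, d = d)
}

#' Fit configuration
#'
#' @param seed Integer seed for the stochastic search (mandatory; echoed in
#'   the result).
#' @param bounds Named list of length-2 ranges for `A`, `B`, `C` (reals) and
#'   `n` (integers). The defaults envelope the magnitudes typical of fitted
#'   functional-group corrections, with `n` allowed to vary around 6.
#' @param cutoffs Optional tibble `type_a`, `type_b`, `s`, `d` fixing the
#'   cutoff per pair type; when `NULL`, [default_cutoffs()] is applied.
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate,blend_alpha,tournament_k,elite GA
#'   operator settings: blend (BLX-alpha) crossover for reals, uniform
#'   random-reset mutation for `n`, tournament selection, elitist carryover.
#' @param polish Run a Levenberg-Marquardt refinement of the real parameters
#'   at fixed `n` after the GA.
#' @param polish_maxiter Iteration cap for the refinement.
#' @param n_starts Independent GA restarts (distinct derived seeds); the best
#'   run wins.
#' @param init_genomes Optional matrix of genomes (one per row) injected into
#'   the initial population, e.g. to warm-start a fine-typed fit from a
#'   coarse-typed solution.
#' @param tol Stop early once the best chi2 falls at or below this value.
#' @return A list of class `fgc_fit_config`.
#' @export
fit_config <- function(seed,
                       bounds = list(A = c(-5e5, 5e5), B = c(0.5, 8),
                                     C = c(-5e3, 5e3), n = c(1L, 12L)),
                       cutoffs = NULL,
                       pop_size = 200, generations = 500,
                       crossover_rate = 0.9, mutation_rate = 0.15,
                       blend_alpha = 0.5, tournament_k = 3, elite = 2,
                       polish = TRUE, polish_maxiter = 100, n_starts = 1,
                       init_genomes = NULL, tol = 1e-10) {
  if (missing(seed)) abort("a seed is required for the stochastic fit")
  for (p in c("A", "B", "C", "n")) {
    b <- bounds[[p]]
    if (is.null(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      abort(sprintf("bounds for '%s' must be a finite increasing range", p))
    }
  }
  if (pop_size < 2) abort("pop_size must be at least 2")
  structure(list(seed = as.integer(seed), bounds = bounds, cutoffs = cutoffs,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 blend_alpha = blend_alpha, tournament_k = as.integer(tournament_k),
                 elite = as.integer(elite), polish = polish,
                 polish_maxiter = as.integer(polish_maxiter),
                 n_starts = as.integer(n_starts), init_genomes = init_genomes,
                 tol = tol),
            class = "fgc_fit_config")
}

#' Pack / unpack the fit genome
#'
#' The genome concatenates `(A, B, C, n)` over the pair types in canonical
#' key order, so a system with `K` pair types has `4 * K` genes (60 for the
#' 15 pair types of a five-type homodimer, 40 for four types, 24 for three).
#'
#' @param params An `fgc_params` parameter set.
#' @return `pack_genome()` returns a numeric vector of length `4 * K`.
#' @export
pack_genome <- function(params) {
  as.vector(t(as.matrix(params[order(params$key), c("A", "B", "C", "n")])))
}

#' @rdname pack_genome
#' @param genome Numeric vector of length `4 * nrow(cutoffs)`.
#' @param cutoffs Tibble `type_a`, `type_b`, `key`, `s`, `d` in canonical key
#'   order, fixing pair identities and cutoffs.
#' @param provenance Provenance label for the resulting set.
#' @export
unpack_genome <- function(genome, cutoffs, provenance = "genome") {
  K <- nrow(cutoffs)
  if (length(genome) != 4 * K) {
    abort(sprintf("genome length %d does not match 4 x %d pair types",
                  length(genome), K))
  }
  cutoffs <- cutoffs[order(pair_key(cutoffs$type_a, cutoffs$type_b)), ]
  m <- matrix(genome, ncol = 4, byrow = TRUE)
  parameter_set(cutoffs$type_a, cutoffs$type_b, m[, 1], m[, 2], m[, 3],
                round(m[, 4]), cutoffs$s, cutoffs$d, provenance = provenance)
}

# Flatten a dataset into parallel vectors: one entry per intermolecular atom
# pair per data point, with the cutoff precomputed (s, d are fixed during the
# fit, so f_cut never changes).
precompute_fit <- function(dataset, cutoffs) {
  keys <- pair_key(cutoffs$type_a, cutoffs$type_b)
  ord <- order(keys)
  cutoffs <- cutoffs[ord, ]; keys <- keys[ord]
  r_all <- list(); k_all <- list(); p_all <- list()
  for (i in seq_len(nrow(dataset))) {
    ma <- dataset$mol_a[[i]]; mb <- dataset$mol_b[[i]]
    na <- nrow(ma); nb <- nrow(mb)
    ii <- rep(seq_len(na), times = nb); jj <- rep(seq_len(nb), each = na)
    r <- sqrt((mb$x[jj] - ma$x[ii])^2 + (mb$y[jj] - ma$y[ii])^2 +
              (mb$z[jj] - ma$z[ii])^2)
    k <- match(pair_key(ma$type[ii], mb$type[jj]), keys)
    if (anyNA(k)) abort("dataset contains a pair type absent from the cutoff table")
    r_all[[i]] <- r; k_all[[i]] <- k
    p_all[[i]] <- rep.int(i, length(r))
  }
  r <- unlist(r_all); k <- unlist(k_all); pt <- unlist(p_all)
  list(r = r, key_idx = k, point_idx = pt,
       fc = f_cut(r, cutoffs$s[k], cutoffs$d[k]),
       y = dataset$y, w = dataset$w, n_points = nrow(dataset),
       cutoffs = cutoffs, K = nrow(cutoffs))
}

# Model prediction per data point for a genome (A1,B1,C1,n1, A2,...).
eval_genome <- function(pre, genome) {
  idx <- pre$key_idx
  A <- genome[4 * idx - 3]; B <- genome[4 * idx - 2]
  C <- genome[4 * idx - 1]; n <- round(genome[4 * idx])
  contrib <- pre$fc * (A * exp(-B * pre$r) + C * pre$r^(-n))
  rowsum_vec(contrib, pre$point_idx, pre$n_points)
}

chi2_genome <- function(pre, genome) {
  sum(pre$w * (pre$y - eval_genome(pre, genome))^2)
}

#' Weighted least-squares objective
#'
#' `sum_i w_i (y_i - f(x_i))^2` over a fit dataset, where `f` is the dimer
#' correction evaluated with `params` at each stored geometry, in
#' kJ^2/mol^2.
#'
#' @param dataset An `fgc_fitdata` tibble.
#' @param params An `fgc_params` parameter set covering every occurring pair
#'   type.
#' @return The objective value.
#' @export
chi2 <- function(dataset, params) {
  pre <- precompute_fit(dataset, params[, c("type_a", "type_b", "s", "d")])
  chi2_genome(pre, pack_genome(params))
}

run_ga <- function(pre, config, seed) {
  set.seed(seed)
  K <- pre$K; L <- 4L * K
  b <- config$bounds
  lower <- rep(c(b$A[1], b$B[1], b$C[1], b$n[1]), K)
  upper <- rep(c(b$A[2], b$B[2], b$C[2], b$n[2]), K)
  is_n <- rep(c(FALSE, FALSE, FALSE, TRUE), K)
  clamp <- function(g) {
    g <- pmin(pmax(g, lower), upper)
    g[is_n] <- round(g[is_n])
    g
  }
  pop <- t(vapply(seq_len(config$pop_size), function(i) {
    g <- runif(L, lower, upper)
    g[is_n] <- sample(seq(b$n[1], b$n[2]), K, replace = TRUE)
    g
  }, numeric(L)))
  init <- config$init_genomes
  if (!is.null(init)) {
    init <- matrix(init, ncol = L)
    take <- seq_len(min(nrow(init), config$pop_size))
    pop[take, ] <- t(apply(init[take, , drop = FALSE], 1, clamp))
  }
  fitness <- apply(pop, 1, chi2_genome, pre = pre)
  best_hist <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    ord <- order(fitness)
    newpop <- matrix(NA_real_, config$pop_size, L)
    n_elite <- min(config$elite, config$pop_size)
    newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    for (i in seq.int(n_elite + 1, length.out = config$pop_size - n_elite)) {
      pick <- function() {
        cand <- sample.int(config$pop_size, config$tournament_k)
        cand[which.min(fitness[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- p1
      if (runif(1) < config$crossover_rate) {
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        span <- hi - lo
        child <- runif(L, lo - config$blend_alpha * span,
                       hi + config$blend_alpha * span)
        swap <- runif(K) < 0.5
        child[is_n] <- ifelse(swap, p1[is_n], p2[is_n])
      }
      mut <- runif(L) < config$mutation_rate
      if (any(mut & !is_n)) {
        j <- which(mut & !is_n)
        child[j] <- child[j] + rnorm(length(j), 0, 0.1 * (upper[j] - lower[j]))
      }
      if (any(mut & is_n)) {
        j <- which(mut & is_n)
        child[j] <- sample(seq(b$n[1], b$n[2]), length(j), replace = TRUE)
      }
      newpop[i, ] <- clamp(child)
    }
    pop <- newpop
    fitness <- apply(pop, 1, chi2_genome, pre = pre)
    best_hist[gen] <- min(fitness)
    if (gen > 1) best_hist[gen] <- min(best_hist[gen], best_hist[gen - 1])
    if (best_hist[gen] <= config$tol) {
      best_hist <- best_hist[seq_len(gen)]
      break
    }
  }
  i_best <- which.min(fitness)
  list(genome = pop[i_best, ], chi2 = fitness[i_best], history = best_hist)
}

polish_genome <- function(pre, genome, config) {
  K <- pre$K
  is_n <- rep(c(FALSE, FALSE, FALSE, TRUE), K)
  reals <- genome[!is_n]
  b <- config$bounds
  lower <- rep(c(b$A[1], b$B[1], b$C[1]), K)
  upper <- rep(c(b$A[2], b$B[2], b$C[2]), K)
  full <- genome
  resid_fn <- function(p) {
    full[!is_n] <- p
    sqrt(pre$w) * (pre$y - eval_genome(pre, full))
  }
  # reaching maxiter is an accepted outcome, not a user-facing condition
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = reals, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = config$polish_maxiter))),
    error = function(e) NULL)
  if (is.null(fit)) return(genome)
  cand <- genome
  cand[!is_n] <- fit$par
  if (chi2_genome(pre, cand) < chi2_genome(pre, genome)) cand else genome
}

#' Fit correction parameters by genetic-algorithm least squares
#'
#' Runs an elitist generational GA over the packed `(A, B, C, n)` genome for
#' every pair type occurring in the dataset, with fixed per-pair cutoffs, and
#' (by default) polishes the real parameters at fixed `n` with
#' Levenberg-Marquardt. Reproducible bit-exactly for a fixed seed.
#'
#' @param dataset An `fgc_fitdata` tibble (see [fit_dataset()]).
#' @param config An `fgc_fit_config` (see [fit_config()]).
#' @return An object of class `fgc_fit`: fitted `params`, final `chi2`,
#'   best-so-far `chi2_history` (non-increasing), per-point `residuals` and
#'   `fitted` values, the `seed` and `config`.
#' @export
fit_parameters <- function(dataset, config) {
  if (!nrow(dataset)) abort("fit dataset is empty")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  cutoffs <- config$cutoffs
  if (is.null(cutoffs)) {
    pt <- dataset_pair_types(dataset)
    cutoffs <- default_cutoffs(pt$pairs, pt$elements)
  }
  if (!"key" %in% names(cutoffs)) cutoffs$key <- pair_key(cutoffs$type_a, cutoffs$type_b)
  pre <- precompute_fit(dataset, cutoffs)
  runs <- lapply(seq_len(config$n_starts) - 1L, function(k) {
    run_ga(pre, config, config$seed + k)
  })
  best <- runs[[which.min(vapply(runs, `[[`, 0, "chi2"))]]
  genome <- best$genome
  if (config$polish) genome <- polish_genome(pre, genome, config)
  final_chi2 <- chi2_genome(pre, genome)
  history <- c(best$history, final_chi2)
  history <- cummin(history)
  params <- unpack_genome(genome, pre$cutoffs,
                          provenance = sprintf("GA fit (seed %d)", config$seed))
  fitted <- eval_genome(pre, genome)
  structure(list(params = params, chi2 = final_chi2, chi2_history = history,
                 residuals = pre$y - fitted, fitted = fitted,
                 n_points = pre$n_points, seed = config$seed, config = config),
            class = "fgc_fit")
}

#' @export
print.fgc_fit <- function(x, ...) {
  cat(sprintf("<fgc_fit> %d pair types, %d points, chi2 = %.6g kJ^2/mol^2 (seed %d)\n",
              nrow(x$params), x$n_points, x$chi2, x$seed))
  invisible(x)
}

#' Merge atom-type labels in molecules, datasets or cutoff tables
#'
#' Relabels atom types according to a mapping, e.g. collapsing the two
#' oxygen labels of a five-type scheme into one to obtain a nested
#' coarser model.
#'
#' @param dataset An `fgc_fitdata` tibble.
#' @param mapping Named character vector: `old label -> new label`. Labels
#'   absent from the mapping are kept.
#' @return The dataset with all geometries relabelled.
#' @export
merge_types <- function(dataset, mapping) {
  relab <- function(m) {
    hit <- m$type %in% names(mapping)
    m$type[hit] <- unname(mapping[m$type[hit]])
    m
  }
  dataset$mol_a <- lapply(dataset$mol_a, relab)
  dataset$mol_b <- lapply(dataset$mol_b, relab)
  dataset
}

#' Expand a coarse-typed parameter set onto a finer typing
#'
#' Every fine pair type inherits the parameters of the coarse pair type its
#' labels map to — the warm-start genome for nested-model fitting (the finer
#' model can represent any coarser solution exactly).
#'
#' @param params Coarse `fgc_params`.
#' @param fine_cutoffs Tibble `type_a`, `type_b`, `s`, `d` for the fine
#'   scheme.
#' @param mapping Named character vector mapping fine labels to coarse
#'   labels.
#' @return An `fgc_params` set over the fine pair types.
#' @export
expand_params <- function(params, fine_cutoffs, mapping) {
  to_coarse <- function(lab) ifelse(lab %in% names(mapping), unname(mapping[lab]), lab)
  keys <- pair_key(to_coarse(fine_cutoffs$type_a), to_coarse(fine_cutoffs$type_b))
  idx <- param_rows(params, keys)
  parameter_set(fine_cutoffs$type_a, fine_cutoffs$type_b,
                params$A[idx], params$B[idx], params$C[idx], params$n[idx],
                fine_cutoffs$s, fine_cutoffs$d,
                provenance = "expanded from coarser typing")
}
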