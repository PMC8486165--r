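# Pair types and correction parameter sets. A pair type is an unordered pair
# of atom-type labels stored in canonical (lexicographic) order; a parameter
# set maps pair types to the correction parameters A (kJ/mol), B (1/A),
# C (kJ mol^-1 A^n), integer n, and the fixed cutoff constants s, d.

#' Canonical pair key
#'
#' @param type_a,type_b Atom-type labels (vectorised).
#' @return Character vector `"a:b"` with the two labels sorted, so
#'   `pair_key(x, y) == pair_key(y, x)`.
#' @export
pair_key <- function(type_a, type_b) {
  paste(pmin(type_a, type_b), pmax(type_a, type_b), sep = ":")
}

#' Enumerate the pair types of a dimer
#'
#' For a homodimer (`same_species = TRUE`) of a molecule with `T` distinct
#' labels this yields all unordered pairs with repetition, `T(T+1)/2` keys;
#' for a heterodimer it yields the distinct canonical cross pairs
#' (`T_a * T_b` when the label sets are disjoint).
#'
#' @param types_a,types_b Character vectors (or sets) of atom-type labels.
#' @param same_species Logical; is this a homodimer of one molecular species?
#' @return A tibble with columns `type_a`, `type_b` (canonical order) and
#'   `key`, sorted by key.
#' @export
enumerate_pair_types <- function(types_a, types_b = types_a, same_species = TRUE) {
  types_a <- unique(as.character(types_a))
  types_b <- unique(as.character(types_b))
  if (!length(types_a) || !length(types_b)) abort("label sets must be non-empty")
  if (same_species) {
    labs <- sort(unique(c(types_a, types_b)))
    idx <- which(upper.tri(diag(length(labs)), diag = TRUE), arr.ind = TRUE)
    a <- labs[idx[, 1]]; b <- labs[idx[, 2]]
  } else {
    g <- expand.grid(a = types_a, b = types_b, stringsAsFactors = FALSE)
    a <- pmin(g$a, g$b); b <- pmax(g$a, g$b)
  }
  out <- tibble::tibble(type_a = pmin(a, b), type_b = pmax(a, b),
                        key = pair_key(a, b))
  out <- dplyr::distinct(dplyr::arrange(out, .data$key))
  out
}

#' Construct a correction parameter set
#'
#' @param type_a,type_b Atom-type labels per row (stored canonically).
#' @param A Pre-exponential amplitude, kJ/mol (either sign).
#' @param B Exponential range, 1/Angstrom (positive).
#' @param C Inverse-power amplitude, kJ mol^-1 Angstrom^n (either sign).
#' @param n Positive integer inverse-power exponent.
#' @param s Cutoff steepness (positive).
#' @param d Cutoff midpoint in Angstrom: the distance where the damping
#'   function equals 1/2.
#' @param provenance Free-text label for where the values come from.
#' @return A tibble of class `fgc_params`, one row per pair type.
#' @export
parameter_set <- function(type_a, type_b, A, B, C, n, s = 10, d = 1,
                          provenance = "") {
  if (any(B <= 0)) abort("B must be positive")
  if (any(n < 1) || any(n != round(n))) abort("n must be a positive integer")
  if (any(s <= 0) || any(d <= 0)) abort("cutoff constants s and d must be positive")
  ta <- pmin(type_a, type_b)
  tb <- pmax(type_a, type_b)
  ps <- tibble::tibble(
    type_a = ta, type_b = tb,
    A = as.numeric(A), B = as.numeric(B), C = as.numeric(C),
    n = as.integer(round(n)),
    s = rep_len(as.numeric(s), length(A)), d = rep_len(as.numeric(d), length(A))
  )
  ps$key <- pair_key(ps$type_a, ps$type_b)
  if (anyDuplicated(ps$key)) {
    abort(sprintf("duplicate pair key '%s' in parameter set", ps$key[duplicated(ps$key)][1]))
  }
  ps <- dplyr::arrange(ps, .data$key)
  attr(ps, "provenance") <- provenance
  class(ps) <- c("fgc_params", class(ps))
  ps
}

#' Parameters fitted for the formic acid homodimer
#'
#' The packaged 15-row parameter set for the five formic acid atom types
#' (`C`, `O`, `OH`, `HO`, `HCO`): `A`, `B`, `C` to two decimals, integer `n`,
#' steepness `s = 10` for every pair and per-pair cutoff midpoints `d`.
#' Energies in kJ/mol, distances in Angstrom.
#'
#' @return An `fgc_params` parameter set with 15 rows.
#' @export
formic_acid_dimer_params <- function() {
  read_params(system.file("extdata", "formic_acid_dimer_params.csv",
                          package = "fgcorr", mustWork = TRUE))
}

#' Read / write parameter sets as CSV
#'
#' Flat CSV with columns `type_a`, `type_b`, `A`, `B`, `C`, `n`, `s`, `d`.
#' Decimal strings round-trip exactly at the written precision.
#'
#' @param path CSV path.
#' @return `read_params()` returns an `fgc_params` set; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  # parse numerics from text with strtod for correctly rounded round-trips
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  for (col in intersect(c("A", "B", "C", "s", "d"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("n" %in% names(df)) df$n <- as.integer(df$n)
  need <- c("type_a", "type_b", "A", "B", "C", "n", "s", "d")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("parameter file missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  parameter_set(df$type_a, df$type_b, df$A, df$B, df$C, df$n, df$s, df$d,
                provenance = path)
}

#' @rdname read_params
#' @param params An `fgc_params` parameter set.
#' @export
write_params <- function(params, path) {
  out <- params[, c("type_a", "type_b", "A", "B", "C", "n", "s", "d")]
  # %.17g guarantees the decimal strings re-parse to bit-identical doubles
  for (col in c("A", "B", "C", "s", "d")) out[[col]] <- sprintf("%.17g", out[[col]])
  readr::write_csv(out, path)
  invisible(path)
}

# Row indices into `params` for each canonical pair key; errors on a missing
# key (silent zeros would mask typing bugs).
param_rows <- function(params, keys) {
  idx <- match(keys, params$key)
  if (anyNA(idx)) {
    abort(sprintf("no parameters for pair type(s): %s",
                  paste(unique(keys[is.na(idx)]), collapse = ", ")))
  }
  idx
}
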