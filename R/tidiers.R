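# broom-style accessors for fitted objects.

#' Tidy a fitted correction
#'
#' One row per pair type with the fitted `A`, `B`, `C`, `n` and the fixed
#' cutoff constants.
#'
#' @param x An `fgc_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fgc_fit
#' @export
tidy.fgc_fit <- function(x, ...) {
  tibble::as_tibble(x$params[, c("type_a", "type_b", "key",
                                 "A", "B", "C", "n", "s", "d")])
}

#' One-row summary of a fit
#'
#' @param x An `fgc_fit`.
#' @param ... Unused.
#' @return A tibble with the objective value, per-point RMSE, problem size
#'   and seed.
#' @method glance fgc_fit
#' @export
glance.fgc_fit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2,
    rmse = sqrt(mean(x$residuals^2)),
    n_points = x$n_points,
    n_pair_types = nrow(x$params),
    n_parameters = 4L * nrow(x$params),
    generations = length(x$chi2_history),
    seed = x$seed
  )
}

#' @method tidy fgc_metrics
#' @export
tidy.fgc_metrics <- function(x, ...) tibble::as_tibble(unclass(x))
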