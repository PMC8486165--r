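# ggplot2 views of curves, fits and correlation reports.

#' Plot energy curves
#'
#' Energy against attack-atom separation, one panel per orientation, colour
#' by energy kind.
#'
#' @param object An `fgc_curves` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fgc_curves
#' @export
autoplot.fgc_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$energy,
                                       colour = .data$energy_kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$orientation_id), scales = "free_y") +
    ggplot2::labs(x = "attack-atom separation (Å)", y = "energy (kJ/mol)",
                  colour = NULL)
}

#' Plot the objective trajectory of a fit
#'
#' Best-so-far chi2 per generation on a log scale.
#'
#' @param object An `fgc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fgc_fit
#' @export
autoplot.fgc_fit <- function(object, ...) {
  df <- tibble::tibble(generation = seq_along(object$chi2_history),
                       chi2 = object$chi2_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$chi2)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = expression(chi^2 ~ "(kJ"^2 * "/mol"^2 * ")"))
}

#' Scatter plot of a correlation report
#'
#' Model against reference interaction energies with the identity line and
#' the fitted regression.
#'
#' @param object An `fgc_metrics` report (from [correlation_report()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fgc_metrics
#' @export
autoplot.fgc_metrics <- function(object, ...) {
  pts <- attr(object, "points")
  if (is.null(pts)) abort("this metrics report carries no point data")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$ref, y = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "reference energy (kJ/mol)", y = "model energy (kJ/mol)",
                  title = object$label)
}
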