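# Error statistics for model-vs-reference interaction energy sets. The bias
# convention is fixed as mean(reference - model): a model whose interaction
# energies are less negative than the reference on an attractive set (i.e.
# one that under-binds) has a negative MBE.

check_pair <- function(ref, model) {
  if (length(ref) != length(model)) abort("ref and model must have equal length")
  if (!length(ref)) abort("need at least one point")
}

#' Mean absolute error
#'
#' @param ref,model Energy vectors of equal length, kJ/mol.
#' @return `mean(abs(ref - model))`.
#' @export
mae <- function(ref, model) {
  check_pair(ref, model)
  mean(abs(ref - model))
}

#' Mean bias error
#'
#' `mean(ref - model)`: negative when the model under-binds an attractive
#' set relative to the reference.
#'
#' @inheritParams mae
#' @return The signed mean difference, kJ/mol.
#' @export
mbe <- function(ref, model) {
  check_pair(ref, model)
  mean(ref - model)
}

#' Error and linear-correlation report for one model
#'
#' Ordinary least-squares regression of the model energies on the reference
#' energies (model on the ordinate), plus MAE/MBE and the energy range.
#' Perfect agreement gives slope 1, intercept 0, r^2 = 1 and zero errors.
#'
#' @inheritParams mae
#' @param label Model name for the report row.
#' @return A one-row tibble of class `fgc_metrics` with columns `label`,
#'   `n_points`, `mae`, `mbe`, `slope`, `intercept`, `r2`, `ref_min`,
#'   `ref_max`. The paired energies are kept as an attribute for plotting.
#' @export
correlation_report <- function(ref, model, label = "model") {
  check_pair(ref, model)
  if (length(ref) < 2) abort("correlation needs at least two points")
  if (diff(range(ref)) == 0) abort("reference energies are constant; correlation undefined")
  fit <- lm(model ~ ref, data = data.frame(ref = ref, model = model))
  out <- tibble::tibble(
    label = label, n_points = length(ref),
    mae = mae(ref, model), mbe = mbe(ref, model),
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r2 = stats::cor(ref, model)^2,
    ref_min = min(ref), ref_max = max(ref)
  )
  attr(out, "points") <- tibble::tibble(ref = ref, model = model, label = label)
  class(out) <- c("fgc_metrics", class(out))
  out
}
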