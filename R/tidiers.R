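#' Tidy a Cox fit
#'
#' One row per model term with the log hazard ratio (`estimate`), the
#' hazard ratio and its Wald 95% confidence interval, and the Wald P value.
#'
#' @param x A [fit_cox()] result.
#' @param ... Ignored.
#' @return A tibble: `term`, `estimate`, `hr`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @method tidy cna_cox
#' @export
tidy.cna_cox <- function(x, ...) {
  x$terms
}

#' One-row model summary of a Cox fit
#'
#' @param x A [fit_cox()] result.
#' @param ... Ignored.
#' @return A tibble: `n`, `n_events`, `concordance`, `logLik`, `converged`,
#'   `stratified`.
#' @method glance cna_cox
#' @export
glance.cna_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    concordance = unname(x$fit$concordance["concordance"]),
    logLik = x$fit$loglik[length(x$fit$loglik)],
    converged = x$converged, stratified = x$stratified)
}

#' Tidy a Kaplan-Meier comparison
#'
#' Returns the pairwise comparisons (hazard ratio, Wald interval/P, log-rank
#' P) of a [km_compare()] result.
#'
#' @param x A [km_compare()] result.
#' @param ... Ignored.
#' @return The `pairwise` tibble.
#' @method tidy cna_km
#' @export
tidy.cna_km <- function(x, ...) {
  x$pairwise
}

#' One-row-per-group summary of a Kaplan-Meier comparison
#'
#' @param x A [km_compare()] result.
#' @param ... Ignored.
#' @return The `medians` tibble (group, n, n_events, median survival).
#' @method glance cna_km
#' @export
glance.cna_km <- function(x, ...) {
  x$medians
}
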