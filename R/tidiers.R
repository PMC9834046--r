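#' Tidy a fitted PA model
#'
#' One row per PA effect estimated by the fit (one for binary models, two
#' for abundance and productivity models).
#'
#' @param x A `"pa_fit"` object.
#' @param ... Unused.
#' @return A tibble with `species_id`, `metric`, `designation`, `beta`,
#'   `se`, `p_value`, `n_units`, `excluded`, `reason`, `dispersion`.
#' @export
tidy.pa_fit <- function(x, ...) x$effects

#' @rdname tidy.pa_fit
#' @export
glance.pa_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_units = nrow(x$design$data),
    n_coef = x$design$n_coef,
    converged = if (is.null(x$model)) NA else isTRUE(x$model$converged),
    deviance = if (is.null(x$model)) NA_real_ else x$model$deviance,
    dispersion = x$effects$dispersion[1],
    theta = x$theta %||% NA_real_
  )
}

#' Tidy a phylogenetic trait regression
#'
#' @param x A `"pa_phylo_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`, `se`,
#'   `conf_low`, `conf_high`, and for MCMC fits `ess`).
#' @export
tidy.pa_phylo_fit <- function(x, ...) x$coefficients

#' @rdname tidy.pa_phylo_fit
#' @export
glance.pa_phylo_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n,
                 sigma2_phylo = x$sigma2_phylo,
                 sigma2_resid = x$sigma2_resid,
                 converged = isTRUE(x$convergence))
}

#' Tidy a matched set
#'
#' @param x A `"pa_matched"` object.
#' @param ... Unused.
#' @return The pairs tibble (`treated_id`, `control_id`, `distance`).
#' @export
tidy.pa_matched <- function(x, ...) x$pairs

#' @rdname tidy.pa_matched
#' @export
glance.pa_matched <- function(x, ...) {
  tibble::tibble(
    designation = x$designation,
    n_treated = sum(x$roles$role == "treated"),
    n_control = sum(x$roles$role == "control"),
    n_pairs = nrow(x$pairs),
    n_unmatched = length(x$unmatched_treated),
    worst_smd_after = max(abs(x$balance$smd_after)),
    n_imbalanced = sum(x$balance$flag_imbalanced)
  )
}
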