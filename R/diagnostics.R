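#' Parametric-bootstrap zero-inflation check
#'
#' Simulates `nsim` response vectors from the fitted model and compares the
#' observed number of zeros with the simulated distribution; the model is
#' flagged zero-inflated when the observed count exceeds the simulated 99th
#' percentile.
#'
#' @param fit A `"pa_fit"` from one of the model-fitting functions.
#' @param nsim Number of bootstrap replicates.
#' @param seed Seed for the simulation.
#' @return A list with `observed_zeros`, `boot_q99` and logical `flagged`.
#' @export
check_zero_inflation <- function(fit, nsim = 200, seed = 1) {
  assert_that(!is.null(fit$model), "fit has no underlying model")
  mu <- stats::fitted(fit$model)
  y <- fit$model$y
  withr::with_seed(seed, {
    zeros <- if (fit$family == "nb") {
      theta <- fit$model$family$getTheta(TRUE)
      vapply(seq_len(nsim), function(i) {
        sum(rnbinom(length(mu), mu = mu, size = theta) == 0)
      }, numeric(1))
    } else if (is.matrix(y)) {  # events-trials
      n_tot <- rowSums(y)
      vapply(seq_len(nsim), function(i) {
        sum(rbinom(length(mu), n_tot, mu) == 0)
      }, numeric(1))
    } else {
      vapply(seq_len(nsim), function(i) {
        sum(rbinom(length(mu), 1, mu) == 0)
      }, numeric(1))
    }
  })
  obs <- if (is.matrix(y)) sum(y[, 1] == 0) else sum(y == 0)
  q99 <- quantile(zeros, 0.99, names = FALSE)
  list(observed_zeros = obs, boot_q99 = q99, flagged = obs > q99)
}

#' Cross-species outlier and overdispersion exclusions
#'
#' Applies the post-fit exclusion rules to an effects table: binary and
#' binomial fits with Pearson dispersion ratio above
#' `dispersion_threshold` are excluded as `"overdispersed"`, and, within
#' each metric-designation group, effects further than `iqr_mult` times the
#' across-species IQR from the across-species median are excluded as
#' `"outlier"`. Already-excluded rows are left untouched and do not
#' contribute to the median/IQR.
#'
#' @param effects A `"pa_effects"` tibble from [fit_species_effects()].
#' @param dispersion_threshold Pearson chi-square / df ratio above which a
#'   binary/binomial fit is excluded.
#' @param iqr_mult Multiplier of the IQR in the outlier rule.
#' @return The effects tibble with updated `excluded`/`reason`.
#' @export
diagnose_and_exclude <- function(effects, dispersion_threshold = 2,
                                 iqr_mult = 5) {
  binaryish <- c("occurrence", "colonization", "persistence",
                 "productivity", "productivity_trend")
  effects |>
    dplyr::mutate(
      .over = !.data$excluded & .data$metric %in% binaryish &
        !is.na(.data$dispersion) &
        .data$dispersion > dispersion_threshold,
      excluded = .data$excluded | .data$.over,
      reason = dplyr::if_else(.data$.over, "overdispersed", .data$reason)
    ) |>
    dplyr::group_by(.data$metric, .data$designation) |>
    dplyr::mutate(
      .med = median(.data$beta[!.data$excluded], na.rm = TRUE),
      .iqr = IQR(.data$beta[!.data$excluded], na.rm = TRUE),
      .out = !.data$excluded & is.finite(.data$.iqr) &
        abs(.data$beta - .data$.med) > iqr_mult * .data$.iqr,
      excluded = .data$excluded | .data$.out,
      reason = dplyr::if_else(.data$.out, "outlier", .data$reason)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::starts_with("."))
}
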