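#' Plot a cross-species effect summary
#'
#' Headline figure: per metric-designation, bars of the percentage of
#' species with significantly positive/negative PA associations and a
#' point-range of the mean effect with its 95% confidence interval.
#'
#' @param object A `"pa_summary"` from [summarize_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_summary <- function(object, ...) {
  bars <- object |>
    dplyr::mutate(pos = 100 * .data$n_pos_sig / pmax(1, .data$n_total),
                  neg = -100 * .data$n_neg_sig / pmax(1, .data$n_total)) |>
    tidyr::pivot_longer(c("pos", "neg"), names_to = "direction",
                        values_to = "pct")
  ggplot2::ggplot(bars) +
    ggplot2::geom_col(ggplot2::aes(x = .data$metric, y = .data$pct,
                                   fill = .data$direction),
                      width = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_pointrange(
      data = object,
      ggplot2::aes(x = .data$metric, y = 100 * .data$mean_effect,
                   ymin = 100 * (.data$mean_effect - 1.96 * .data$se),
                   ymax = 100 * (.data$mean_effect + 1.96 * .data$se)),
      colour = "grey20", size = 0.3) +
    ggplot2::facet_wrap(~designation) +
    ggplot2::scale_fill_manual(values = c(pos = "#2166ac", neg = "#b2182b"),
                               labels = c(pos = "sig. positive",
                                          neg = "sig. negative"),
                               name = NULL) +
    ggplot2::labs(x = NULL,
                  y = "% of species (bars); mean effect x100 (points)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Love plot of covariate balance
#'
#' Absolute standardized mean differences before and after matching, with
#' the 0.25 balance guideline.
#'
#' @param object A `"pa_matched"` from [mahalanobis_match()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_matched <- function(object, ...) {
  long <- object$balance |>
    tidyr::pivot_longer(c("smd_before", "smd_after"), names_to = "stage",
                        values_to = "smd") |>
    dplyr::mutate(stage = factor(.data$stage,
                                 levels = c("smd_before", "smd_after"),
                                 labels = c("before", "after")))
  ggplot2::ggplot(long, ggplot2::aes(x = abs(.data$smd),
                                     y = .data$covariate,
                                     colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.25, linetype = 2) +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL,
                  title = paste0("Balance, ", object$designation,
                                 " (>", 100 * object$threshold,
                                 "% coverage vs none)")) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of trait models
#'
#' Point-ranges of the trait coefficients (95% intervals) from
#' [run_trait_models()], faceted by metric.
#'
#' @param object A `"pa_trait_results"` tibble.
#' @param model Which model set to show (default `"ecological"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_trait_results <- function(object, model = "ecological", ...) {
  dat <- object |>
    dplyr::filter(.data$model_id == model, .data$term != "(Intercept)")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$term,
                                    xmin = .data$conf_low,
                                    xmax = .data$conf_high,
                                    colour = .data$designation)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "coefficient (95% interval)", y = NULL,
                  title = paste0("Trait model: ", model)) +
    ggplot2::theme_minimal()
}

#' Plot community-metric PA associations
#'
#' Point-ranges of the PA state and PA-by-year trend coefficients for each
#' community metric.
#'
#' @param object A `"pa_community_fit"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_community_fit <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate, y = .data$metric,
                               xmin = .data$estimate - 1.96 * .data$se,
                               xmax = .data$estimate + 1.96 * .data$se,
                               colour = .data$designation)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
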