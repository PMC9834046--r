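# Wald row for one parametric coefficient of an mgcv fit. Uses coef/vcov
# directly (the same quantities summary.gam tabulates) so degenerate smooth
# blocks cannot derail the parametric Wald test.
wald_row <- function(model, term) {
  cf <- coef(model)
  assert_that(term %in% names(cf), paste("term", term, "not in fit"))
  est <- unname(cf[term])
  se <- unname(sqrt(diag(stats::vcov(model))[term]))
  p <- 2 * pnorm(-abs(est / se))
  c(beta = est, se = se, p_value = p)
}

effect_row <- function(species_id, metric, designation, beta = NA_real_,
                       se = NA_real_, p_value = NA_real_, n_units = NA_integer_,
                       excluded = FALSE, reason = NA_character_,
                       dispersion = NA_real_) {
  tibble::tibble(species_id = species_id, metric = metric,
                 designation = designation, beta = unname(beta),
                 se = unname(se), p_value = unname(p_value),
                 n_units = as.integer(n_units),
                 excluded = unname(excluded), reason = reason,
                 dispersion = unname(dispersion))
}

pearson_dispersion <- function(model) {
  sum(stats::residuals(model, type = "pearson")^2) / stats::df.residual(model)
}

new_pa_fit <- function(model, design, effects, family) {
  structure(list(model = model, design = design, effects = effects,
                 family = family), class = "pa_fit")
}

#' @export
print.pa_fit <- function(x, ...) {
  cat("<pa_fit> ", x$family, ", ", nrow(x$design$data), " units\n", sep = "")
  print(x$effects)
  invisible(x)
}

fit_gam <- function(design, family, use_bam = nrow(design$data) > 5000) {
  if (use_bam) {
    mgcv::bam(design$formula, family = family, data = design$data,
              discrete = TRUE)
  } else {
    mgcv::gam(design$formula, family = family, data = design$data,
              method = "REML")
  }
}

#' Fit a binary PA-association model
#'
#' Penalized binomial-logit regression (smooth and random blocks penalized,
#' everything else unpenalized maximum likelihood) for occurrence,
#' colonization or persistence. The reported effect is the Wald estimate of
#' the linear PA-fraction coefficient. Exclusion rules: `n_units` below the
#' number of model coefficients (`"n_lt_k"`), apparent separation
#' (|beta| > 15 on the logit scale, `"fit_failure"`), or fit errors.
#'
#' @param design A [build_design()] object whose response is a 0/1 column.
#' @param metric Metric label stored on the effect row.
#' @param species_id Species label stored on the effect row.
#' @return A `"pa_fit"` object; its `$effects` is a one-row effects tibble
#'   (see [fit_species_effects()] for the column contract).
#' @export
fit_binary_model <- function(design, metric = "occurrence",
                             species_id = "sp") {
  n <- nrow(design$data)
  base <- function(...) effect_row(species_id, metric, design$designation,
                                   n_units = n, ...)
  if (n < design$n_coef) {
    return(new_pa_fit(NULL, design,
                      base(excluded = TRUE, reason = "n_lt_k"), "binomial"))
  }
  model <- tryCatch(fit_gam(design, stats::binomial()), error = identity)
  if (inherits(model, "error")) {
    return(new_pa_fit(NULL, design,
                      base(excluded = TRUE, reason = "fit_failure"), "binomial"))
  }
  w <- wald_row(model, "pa")
  disp <- pearson_dispersion(model)
  eff <- if (abs(w["beta"]) > 15) {
    base(beta = w["beta"], se = w["se"], p_value = w["p_value"],
         excluded = TRUE, reason = "fit_failure", dispersion = disp)
  } else {
    base(beta = w["beta"], se = w["se"], p_value = w["p_value"],
         dispersion = disp)
  }
  new_pa_fit(model, design, eff, "binomial")
}

#' Fit the negative-binomial abundance model
#'
#' Log-link negative-binomial regression of the per-square-year visit-maximum
#' count, with quadratic continuous year, a year-factor random effect, the
#' effort offset and the PA term plus its interaction with linear year. The
#' NB size parameter is estimated by outer optimization of the (restricted)
#' marginal likelihood. Returns two effects: the PA main effect
#' (`abundance`) and the PA-by-year interaction (`abundance_trend`).
#' Exclusions: non-convergence (`"fit_failure"`), estimated size below 1e-3
#' (`"overdispersed"`), `n < k` (`"n_lt_k"`).
#'
#' @inheritParams fit_binary_model
#' @param design Design built with
#'   `terms = c("year", "pa_trend", "year_random", "smooth")` and the
#'   `n_transect_squares` offset; response is the count column.
#' @return A `"pa_fit"` with a two-row `$effects` tibble; `$theta` holds the
#'   estimated NB size.
#' @export
fit_abundance_model <- function(design, species_id = "sp") {
  n <- nrow(design$data)
  base <- function(metric, ...) effect_row(species_id, metric,
                                           design$designation,
                                           n_units = n, ...)
  both <- function(...) dplyr::bind_rows(base("abundance", ...),
                                         base("abundance_trend", ...))
  if (n < design$n_coef) {
    return(new_pa_fit(NULL, design, both(excluded = TRUE, reason = "n_lt_k"),
                      "nb"))
  }
  model <- tryCatch(fit_gam(design, mgcv::nb()), error = identity)
  if (inherits(model, "error") || !isTRUE(model$converged)) {
    return(new_pa_fit(NULL, design,
                      both(excluded = TRUE, reason = "fit_failure"), "nb"))
  }
  theta <- model$family$getTheta(TRUE)
  disp <- pearson_dispersion(model)
  if (theta < 1e-3) {
    eff <- both(excluded = TRUE, reason = "overdispersed", dispersion = disp)
  } else {
    w_ab <- wald_row(model, "pa")
    w_tr <- wald_row(model, "pa:yearc")
    eff <- dplyr::bind_rows(
      base("abundance", beta = w_ab["beta"], se = w_ab["se"],
           p_value = w_ab["p_value"], dispersion = disp),
      base("abundance_trend", beta = w_tr["beta"], se = w_tr["se"],
           p_value = w_tr["p_value"], dispersion = disp)
    )
  }
  fit <- new_pa_fit(model, design, eff, "nb")
  fit$theta <- theta
  fit
}

#' Filter constant-effort ringing records
#'
#' Applies the completeness rules used for productivity data: a site-year is
#' omitted when fewer than `min_visits` early (of the first six) or fewer
#' than `min_visits` late (of the last six) visits were made, and a
#' site-year-species record is omitted when fewer than `min_captures`
#' juveniles plus adults were caught.
#'
#' @param ringing Ringing records from [simulate_ringing()] (columns
#'   `n_juv`, `n_ad`, `n_early_visits`, `n_late_visits`).
#' @param min_visits,min_captures Rule thresholds (defaults 4 and 10).
#' @return The filtered tibble.
#' @export
filter_ces_records <- function(ringing, min_visits = 4, min_captures = 10) {
  ringing |>
    dplyr::filter(.data$n_early_visits >= min_visits,
                  .data$n_late_visits >= min_visits,
                  .data$n_juv + .data$n_ad >= min_captures)
}

#' Fit the events-trials productivity model
#'
#' Binomial-logit regression of the juvenile proportion of captures
#' (`cbind(n_juv, n_ad)` events-trials form) on covariates, the PA term and
#' its interaction with linear year. Apply [filter_ces_records()] before
#' building the design. Returns two effects: `productivity` (PA main
#' effect) and `productivity_trend` (PA-by-year). All-juvenile or all-adult
#' data after filtering are excluded as `"fit_failure"`.
#'
#' @inheritParams fit_binary_model
#' @param design Design with `response = "cbind(n_juv, n_ad)"` and year/PA
#'   trend terms.
#' @return A `"pa_fit"` with a two-row `$effects` tibble.
#' @export
fit_productivity_model <- function(design, species_id = "sp") {
  n <- nrow(design$data)
  base <- function(metric, ...) effect_row(species_id, metric,
                                           design$designation,
                                           n_units = n, ...)
  both <- function(...) dplyr::bind_rows(base("productivity", ...),
                                         base("productivity_trend", ...))
  if (n < design$n_coef) {
    return(new_pa_fit(NULL, design, both(excluded = TRUE, reason = "n_lt_k"),
                      "binomial"))
  }
  tot_juv <- sum(design$data$n_juv)
  tot_ad <- sum(design$data$n_ad)
  if (tot_juv == 0 || tot_ad == 0) {
    return(new_pa_fit(NULL, design,
                      both(excluded = TRUE, reason = "fit_failure"),
                      "binomial"))
  }
  model <- tryCatch(fit_gam(design, stats::binomial()), error = identity)
  if (inherits(model, "error")) {
    return(new_pa_fit(NULL, design,
                      both(excluded = TRUE, reason = "fit_failure"),
                      "binomial"))
  }
  w_pr <- wald_row(model, "pa")
  disp <- pearson_dispersion(model)
  sep <- abs(w_pr["beta"]) > 15
  eff <- base("productivity", beta = w_pr["beta"], se = w_pr["se"],
              p_value = w_pr["p_value"], excluded = sep,
              reason = ifelse(sep, "fit_failure", NA_character_),
              dispersion = disp)
  if ("pa_trend" %in% design$terms) {
    w_tr <- wald_row(model, "pa:yearc")
    eff <- dplyr::bind_rows(
      eff,
      base("productivity_trend", beta = w_tr["beta"], se = w_tr["se"],
           p_value = w_tr["p_value"], excluded = sep,
           reason = ifelse(sep, "fit_failure", NA_character_),
           dispersion = disp)
    )
  }
  new_pa_fit(model, design, eff, "binomial")
}
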