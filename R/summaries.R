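#' Sign-count test of significant positive versus negative effects
#'
#' Counts species with significantly positive and significantly negative PA
#' coefficients at level `alpha` and tests the balance with an exact
#' two-sided binomial test against p = 0.5 (significant species only); the
#' continuity-uncorrected chi-square statistic is reported alongside.
#'
#' @param beta,p_value Effect estimates and two-sided p-values.
#' @param alpha Significance threshold (default 0.05).
#' @return A one-row tibble: `n_pos_sig`, `n_neg_sig`, `n_total`,
#'   `prop_test_p` (exact; `NA` when no species is significant),
#'   `chisq_stat`, `chisq_p`.
#' @export
#' @examples
#' sign_count_test(c(rep(1, 8), rep(-1, 2)), rep(0.01, 10))$prop_test_p
sign_count_test <- function(beta, p_value, alpha = 0.05) {
  sig <- !is.na(p_value) & p_value < alpha
  n_pos <- sum(sig & beta > 0)
  n_neg <- sum(sig & beta < 0)
  n_sig <- n_pos + n_neg
  if (n_sig == 0) {
    p_exact <- NA_real_
    chisq <- NA_real_
    chisq_p <- NA_real_
  } else {
    p_exact <- binom.test(n_pos, n_sig, 0.5)$p.value
    ct <- suppressWarnings(chisq.test(c(n_pos, n_neg), correct = FALSE))
    chisq <- unname(ct$statistic)
    chisq_p <- ct$p.value
  }
  tibble::tibble(n_pos_sig = n_pos, n_neg_sig = n_neg,
                 n_total = length(beta), prop_test_p = p_exact,
                 chisq_stat = chisq, chisq_p = chisq_p)
}

#' One-sample t-test of the mean effect across species
#'
#' Two-sided one-sample t-test of the species-level PA coefficients against
#' zero, df = n - 1. A degenerate sample (all values identical and nonzero,
#' so the SE is 0) is reported with `t = Inf`, `p = 0` and `degenerate =
#' TRUE`.
#'
#' @param beta Effect estimates (non-excluded species).
#' @return One-row tibble: `mean_effect`, `se`, `t_stat`, `df`, `t_p`,
#'   `degenerate`.
#' @export
#' @examples
#' mean_effect_ttest(c(1, 1, 1, -1))  # t = 1, p ~ 0.391
mean_effect_ttest <- function(beta) {
  beta <- beta[!is.na(beta)]
  n <- length(beta)
  assert_that(n >= 2, "mean-effect t-test needs at least 2 species")
  m <- mean(beta)
  se <- sd(beta) / sqrt(n)
  if (se == 0) {
    t <- if (m == 0) 0 else Inf * sign(m)
    p <- if (m == 0) 1 else 0
    return(tibble::tibble(mean_effect = m, se = se, t_stat = t, df = n - 1,
                          t_p = p, degenerate = m != 0))
  }
  t <- m / se
  tibble::tibble(mean_effect = m, se = se, t_stat = t, df = n - 1,
                 t_p = 2 * pt(-abs(t), n - 1), degenerate = FALSE)
}

#' Paired t-test comparing SPA and SAC effects within species
#'
#' Pairs effects by `species_id` (species missing in either set are
#' dropped) and applies a paired two-sided t-test to the within-species
#' differences (first minus second).
#'
#' @param effects_a,effects_b Effects tibbles (e.g. the SPA and SAC rows of
#'   one metric), each with `species_id` and `beta`.
#' @return One-row tibble: `mean_diff`, `se`, `t_stat`, `df`, `t_p`,
#'   `n_pairs`, `degenerate`.
#' @export
paired_designation_ttest <- function(effects_a, effects_b) {
  pairs <- dplyr::inner_join(
    dplyr::select(effects_a, "species_id", beta_a = "beta"),
    dplyr::select(effects_b, "species_id", beta_b = "beta"),
    by = "species_id"
  ) |>
    dplyr::filter(!is.na(.data$beta_a), !is.na(.data$beta_b))
  assert_that(nrow(pairs) >= 2, "paired t-test needs at least 2 complete pairs")
  res <- mean_effect_ttest(pairs$beta_a - pairs$beta_b)
  dplyr::rename(res, mean_diff = "mean_effect") |>
    dplyr::mutate(n_pairs = nrow(pairs))
}

#' Summarize PA effects across species
#'
#' Aggregates a per-species effects table into one row per
#' metric-designation: significant sign counts with the exact binomial
#' (and chi-square) balance test, and the across-species mean effect with
#' its one-sample t-test. Excluded species never enter counts or means.
#'
#' @param effects A `"pa_effects"` tibble.
#' @param alpha Significance threshold for the sign counts.
#' @return A tibble of class `"pa_summary"`, one row per
#'   metric-designation.
#' @export
summarize_effects <- function(effects, alpha = 0.05) {
  ok <- dplyr::filter(effects, !.data$excluded, !is.na(.data$beta))
  out <- ok |>
    dplyr::arrange(.data$species_id) |>
    dplyr::group_by(.data$metric, .data$designation) |>
    dplyr::group_modify(function(g, key) {
      counts <- sign_count_test(g$beta, g$p_value, alpha)
      tt <- if (nrow(g) >= 2) mean_effect_ttest(g$beta) else
        tibble::tibble(mean_effect = mean(g$beta), se = NA_real_,
                       t_stat = NA_real_, df = NA_real_, t_p = NA_real_,
                       degenerate = FALSE)
      dplyr::bind_cols(counts, tt)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(metric = factor(.data$metric, levels = pa_metrics())) |>
    dplyr::arrange(.data$metric, .data$designation) |>
    dplyr::mutate(metric = as.character(.data$metric))
  structure(out, class = c("pa_summary", class(out)), alpha = alpha)
}
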