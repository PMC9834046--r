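#' Detectability correction
#'
#' Scales a raw count to a density comparable across species by dividing by
#' the species' detection probability.
#'
#' @param count Nonnegative counts.
#' @param detectability Detection probabilities in (0, 1].
#' @return Densities (`count / detectability`).
#' @export
detectability_correct <- function(count, detectability) {
  assert_that(all(detectability > 0 & detectability <= 1),
              "detectability must be in (0, 1]")
  count / detectability
}

#' Species specialisation index (SSI)
#'
#' Coefficient of variation of a species' density across habitat classes:
#' population SD (divide by n) over the mean, by default; `sample_sd = TRUE`
#' switches to the n-1 denominator.
#'
#' @param densities Density of the species in each habitat class (one value
#'   per class, at least two classes).
#' @param sample_sd Use the sample (n-1) SD instead of the population SD.
#' @return The SSI (scale-invariant, >= 0).
#' @export
#' @examples
#' species_specialisation_index(c(5, rep(0, 11)))  # sqrt(11): full specialist
species_specialisation_index <- function(densities, sample_sd = FALSE) {
  assert_that(length(densities) >= 2, "SSI needs at least two habitat classes")
  assert_that(all(densities >= 0), "densities must be nonnegative")
  m <- mean(densities)
  assert_that(m > 0, "SSI undefined for an all-zero density profile")
  s <- if (sample_sd) sd(densities) else
    sqrt(mean((densities - m)^2))
  s / m
}

#' Hill's N2 diversity (inverse Simpson)
#'
#' `1 / sum(p_i^2)` with `p_i` the density proportions. Bounded by 1 and the
#' species richness, with equality at the upper bound iff all present
#' species are equally dense.
#'
#' @param densities Nonnegative densities, at least one positive.
#' @return Hill's N2.
#' @export
#' @examples
#' hill_n2(c(0.8, 0.2))  # 1/0.68
hill_n2 <- function(densities) {
  assert_that(all(densities >= 0), "densities must be nonnegative")
  tot <- sum(densities)
  assert_that(tot > 0, "N2 undefined for an all-zero community")
  p <- densities / tot
  1 / sum(p^2)
}

#' Density-weighted community indices (CSI, CTI)
#'
#' Community specialisation index and community temperature index: the
#' density-weighted means of the per-species SSI and STI over the species
#' present.
#'
#' @param densities Nonnegative densities, at least one positive.
#' @param ssi,sti Per-species SSI and STI values aligned with `densities`.
#' @return A one-row tibble with `csi` and `cti`.
#' @export
#' @examples
#' community_indices(c(3, 1), ssi = c(1, 1), sti = c(10, 20))  # cti 12.5
community_indices <- function(densities, ssi, sti) {
  assert_that(all(densities >= 0) && sum(densities) > 0,
              "community indices need a positive total density")
  tibble::tibble(csi = sum(densities * ssi) / sum(densities),
                 cti = sum(densities * sti) / sum(densities))
}

#' Per square-year community metrics
#'
#' Computes detectability-corrected densities from count records and derives
#' richness, Hill's N2, evenness (N2 / richness), CSI and CTI for every
#' square-year with at least one species present. Species' SSI/STI traits
#' are taken from the species table.
#'
#' @param counts Count records (`square_id`, `species_id`, `year`, `count`).
#' @param species Species tibble with `detectability`, `ssi`, `sti`.
#' @return A tibble of class `"pa_community"`: `square_id`, `year`,
#'   `richness`, `n2`, `evenness`, `csi`, `cti`.
#' @export
community_metrics <- function(counts, species) {
  counts |>
    dplyr::inner_join(
      dplyr::select(species, "species_id", "detectability", "ssi", "sti"),
      by = "species_id") |>
    dplyr::filter(.data$count > 0) |>
    dplyr::mutate(density = detectability_correct(.data$count,
                                                  .data$detectability)) |>
    dplyr::group_by(.data$square_id, .data$year) |>
    dplyr::summarise(
      richness = dplyr::n(),
      n2 = hill_n2(.data$density),
      evenness = .data$n2 / .data$richness,
      csi = sum(.data$density * .data$ssi) / sum(.data$density),
      cti = sum(.data$density * .data$sti) / sum(.data$density),
      .groups = "drop"
    ) |>
    structure(class = c("pa_community", class(tibble::tibble())))
}

#' PA association and trend of a community metric
#'
#' Regresses one community metric on the shared covariate structure plus
#' the designation coverage fraction and its interaction with linear year:
#' richness with a log-link negative-binomial count model, the continuous
#' metrics (n2, evenness, csi, cti) with identity-link Gaussian models.
#' Returns the PA state and PA-by-year trend coefficients with Wald SEs.
#'
#' @param metrics A [community_metrics()] tibble.
#' @param squares Landscape covariate tibble.
#' @param designation One of [pa_designations()].
#' @param which_metrics Metrics to model.
#' @param smooth_k Tensor-smooth marginal basis dimension.
#' @return A tibble of class `"pa_community_fit"`: `metric`, `designation`,
#'   `term` (`"pa"`/`"pa_trend"`), `estimate`, `se`, `p_value`, `n_units`.
#' @export
fit_community_models <- function(metrics, squares, designation = "ALL",
                                 which_metrics = c("richness", "n2",
                                                   "evenness", "csi", "cti"),
                                 smooth_k = 4) {
  assert_that(dplyr::n_distinct(metrics$year) >= 3,
              "community trend models need at least 3 years")
  purrr::map_dfr(which_metrics, function(m) {
    units <- metrics |>
      dplyr::select("square_id", "year", value = dplyr::all_of(m)) |>
      dplyr::filter(!is.na(.data$value))
    if (sd(units$value) == 0) {
      # a constant metric carries no association with anything
      return(tibble::tibble(metric = m, designation = designation,
                            term = c("pa", "pa_trend"), estimate = 0,
                            se = 0, p_value = NA_real_,
                            n_units = nrow(units)))
    }
    des <- build_design(units, squares, designation, response = "value",
                        terms = c("year", "pa_trend", "year_random", "smooth"),
                        smooth_k = smooth_k)
    fam <- if (m == "richness") mgcv::nb() else stats::gaussian()
    model <- tryCatch(fit_gam(des, fam), error = identity)
    if (inherits(model, "error")) {
      return(tibble::tibble(metric = m, designation = designation,
                            term = c("pa", "pa_trend"),
                            estimate = NA_real_, se = NA_real_,
                            p_value = NA_real_, n_units = nrow(units)))
    }
    w_pa <- wald_row(model, "pa")
    w_tr <- wald_row(model, "pa:yearc")
    tibble::tibble(
      metric = m, designation = designation,
      term = c("pa", "pa_trend"),
      estimate = c(w_pa["beta"], w_tr["beta"]),
      se = c(w_pa["se"], w_tr["se"]),
      p_value = c(w_pa["p_value"], w_tr["p_value"]),
      n_units = nrow(units)
    )
  }) |>
    structure(class = c("pa_community_fit", class(tibble::tibble())))
}
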