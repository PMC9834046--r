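#' Fit PA-association models for every species, metric and designation
#'
#' The workhorse of the per-species stage. For the atlas metrics it applies
#' the breeding-evidence filter, classifies transitions and applies the
#' native / minimum-tetrad species filter; for abundance it applies the
#' proportional recorded-squares screen; for productivity it applies the
#' visit and capture-count filters. Each retained species-metric-designation
#' combination is fitted with the appropriate model
#' ([fit_binary_model()], [fit_abundance_model()],
#' [fit_productivity_model()]) and the PA coefficients are collected.
#'
#' @param sim A data set from [simulate_survey_data()] (or a list with the
#'   same elements built from real tables).
#' @param metrics Metrics to fit (subset of [pa_metrics()]; trend metrics are
#'   fitted together with their parent model).
#' @param designations Designations to fit (subset of [pa_designations()]).
#' @param smooth_k Marginal tensor-smooth basis dimension.
#' @param min_tetrads Atlas species-inclusion threshold (occupied tetrads).
#' @param min_square_fraction Abundance screen: minimum mean fraction of
#'   squares on which a species is recorded per year. The real-data screen
#'   is an absolute 100 squares/year; a proportional rule scales to
#'   synthetic landscape sizes.
#' @param keep_models Keep the underlying `"pa_fit"` objects (memory-heavy).
#' @return A tibble of class `"pa_effects"`, one row per
#'   species-metric-designation: `species_id`, `metric`, `designation`,
#'   `beta`, `se`, `p_value`, `n_units`, `excluded`, `reason`, `dispersion`.
#'   If `keep_models`, the fits are attached as attribute `"models"`.
#' @export
fit_species_effects <- function(sim,
                                metrics = pa_metrics(),
                                designations = "ALL",
                                smooth_k = 4,
                                min_tetrads = 20,
                                min_square_fraction = 0.05,
                                keep_models = FALSE) {
  metrics <- match.arg(metrics, pa_metrics(), several.ok = TRUE)
  designations <- match.arg(toupper(designations), pa_designations(),
                            several.ok = TRUE)
  squares <- sim$squares
  results <- list()
  models <- list()
  keep <- function(fit, id) {
    if (keep_models) models[[id]] <<- fit
    results[[id]] <<- fit$effects
  }

  atlas_metrics <- intersect(metrics, c("occurrence", "colonization",
                                        "persistence"))
  if (length(atlas_metrics) > 0) {
    outcomes <- classify_transitions(filter_breeding_evidence(sim$atlas))
    incl <- species_inclusion_filter(outcomes, sim$species, min_tetrads)
    retained <- incl$species_id[incl$retained]
    for (sp in retained) {
      oc <- dplyr::filter(outcomes, .data$species_id == sp)
      for (m in atlas_metrics) {
        units <- oc[!is.na(oc[[m]]), c("square_id", m)]
        for (d in designations) {
          des <- build_design(units, squares, d, response = m,
                              terms = "smooth", smooth_k = smooth_k)
          keep(fit_binary_model(des, metric = m, species_id = sp),
               paste(sp, m, d, sep = "."))
        }
      }
    }
  }

  if (any(c("abundance", "abundance_trend") %in% metrics)) {
    screen <- sim$counts |>
      dplyr::group_by(.data$species_id, .data$year) |>
      dplyr::summarise(n_rec = sum(.data$count > 0), .groups = "drop_last") |>
      dplyr::summarise(mean_rec = mean(.data$n_rec), .groups = "drop")
    retained <- screen$species_id[
      screen$mean_rec >= min_square_fraction * nrow(squares)]
    for (sp in retained) {
      units <- dplyr::filter(sim$counts, .data$species_id == sp) |>
        dplyr::select("square_id", "year", "count")
      for (d in designations) {
        des <- build_design(units, squares, d, response = "count",
                            terms = c("year", "pa_trend", "year_random",
                                      "smooth"),
                            smooth_k = smooth_k, offset = "n_transect_squares")
        keep(fit_abundance_model(des, species_id = sp),
             paste(sp, "abundance", d, sep = "."))
      }
    }
  }

  if (any(c("productivity", "productivity_trend") %in% metrics)) {
    ces <- filter_ces_records(sim$ringing)
    for (sp in unique(ces$species_id)) {
      units <- dplyr::filter(ces, .data$species_id == sp) |>
        dplyr::select("site_id", "year", "n_juv", "n_ad")
      for (d in designations) {
        des <- build_design(units, squares, d,
                            response = "cbind(n_juv, n_ad)",
                            terms = c("pa_trend", "year_random", "smooth"),
                            smooth_k = smooth_k)
        keep(fit_productivity_model(des, species_id = sp),
             paste(sp, "productivity", d, sep = "."))
      }
    }
  }

  out <- dplyr::bind_rows(results)
  out <- out[out$metric %in% metrics, , drop = FALSE]
  out <- structure(dplyr::as_tibble(out),
                   class = c("pa_effects", class(dplyr::as_tibble(out))))
  if (keep_models) attr(out, "models") <- models
  out
}
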