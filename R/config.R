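#' Simulation configuration
#'
#' Collects every knob of the synthetic monitoring-data generator. The
#' defaults define the package's reference study conditions: per-metric mean
#' true PA slopes equal to the cross-species means reported for the UK
#' avifauna (occurrence 0.49, colonization 0.27, persistence 0.23, abundance
#' 0.25 on the logit/log scale; abundance trend 0), between-species SDs wide
#' enough that species-level responses span negative and positive values, a
#' confounded landscape in which PA coverage increases with elevation and
#' decreases with human density, negative-binomial counts with shared year
#' random effects, and binomial juvenile proportions at ringing sites.
#'
#' @param n_squares Number of 1-km monitoring squares (atlas treats them as
#'   tetrads on the same grid). At least 10.
#' @param n_species Number of species in the pool. At least 3.
#' @param n_years Number of count/ringing years. At least 3.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param confounding_strength Target correlation between `pa_all` and
#'   elevation (and, negatively, log human density).
#' @param overdispersion Negative-binomial size parameter for counts
#'   (variance = mu + mu^2/size).
#' @param year_sd SD of the year random intercepts shared across species
#'   within a stream (a weather proxy).
#' @param effect_mean,effect_sd Named per-metric means and SDs of true PA
#'   slopes (names from [pa_metrics()]).
#' @param linkage_pop Named per-metric coefficient of the true slope on
#'   standardized log population size (negative = rarer species benefit more).
#' @param linkage_change Coefficient of the abundance-trend slope on
#'   standardized log population change (negative = declining species have
#'   more positive trends in PAs).
#' @param zero_pa_fraction Fraction of squares forced to zero PA coverage so
#'   that matching has true controls.
#' @param field_range Range (km) of the Gaussian-kernel random fields used for
#'   all spatially smooth covariates.
#' @param covariate_strength Multiplier on all non-PA covariate effects in the
#'   outcome models; 0 gives flat covariates.
#' @param nonnative_fraction Fraction of species flagged non-native.
#' @param base_occupancy,base_colonization,base_persistence Baseline
#'   probabilities for the atlas stream.
#' @param evidence_probs Multinomial probabilities of
#'   possible/probable/confirmed breeding-evidence codes given true presence.
#' @param false_evidence_rate Probability that a truly absent surveyed tetrad
#'   records a spurious "possible" sighting.
#' @param single_period_fraction Fraction of tetrads surveyed in only one
#'   atlas period.
#' @param count_base_mean Baseline expected count per square-year for a
#'   median-population species.
#' @param ringing_site_fraction Fraction of squares hosting a constant-effort
#'   ringing site.
#' @param ringing_base_total Expected total captures per site-year-species.
#' @param productivity_base_logit Baseline log-odds that a capture is a
#'   juvenile.
#'
#' @return A list of class `"pa_sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_squares = 100, n_species = 5, n_years = 5, seed = 1)
#' cfg$effect_mean[["occurrence"]]
sim_config <- function(n_squares = 1000,
                       n_species = 30,
                       n_years = 15,
                       seed = 1,
                       confounding_strength = 0.6,
                       overdispersion = 1.5,
                       year_sd = 0.15,
                       effect_mean = c(occurrence = 0.49, colonization = 0.27,
                                       persistence = 0.23, abundance = 0.25,
                                       abundance_trend = 0,
                                       productivity = -0.2,
                                       productivity_trend = 0),
                       effect_sd = c(occurrence = 0.9, colonization = 0.8,
                                     persistence = 0.8, abundance = 0.6,
                                     abundance_trend = 0.03,
                                     productivity = 0.5,
                                     productivity_trend = 0.02),
                       linkage_pop = c(occurrence = -0.3, colonization = -0.3,
                                       persistence = -0.3, abundance = -0.3,
                                       abundance_trend = 0, productivity = 0,
                                       productivity_trend = 0),
                       linkage_change = -0.015,
                       zero_pa_fraction = 0.30,
                       field_range = 6,
                       covariate_strength = 1,
                       nonnative_fraction = 0.05,
                       base_occupancy = 0.45,
                       base_colonization = 0.12,
                       base_persistence = 0.80,
                       evidence_probs = c(possible = 0.2, probable = 0.3,
                                          confirmed = 0.5),
                       false_evidence_rate = 0.02,
                       single_period_fraction = 0.15,
                       count_base_mean = 3,
                       ringing_site_fraction = 0.08,
                       ringing_base_total = 12,
                       productivity_base_logit = 0.2) {
  cfg <- list(
    n_squares = as.integer(n_squares),
    n_species = as.integer(n_species),
    n_years = as.integer(n_years),
    seed = as.integer(seed),
    confounding_strength = confounding_strength,
    overdispersion = overdispersion,
    year_sd = year_sd,
    effect_mean = fill_metric(effect_mean, 0),
    effect_sd = fill_metric(effect_sd, 0),
    linkage_pop = fill_metric(linkage_pop, 0),
    linkage_change = linkage_change,
    zero_pa_fraction = zero_pa_fraction,
    field_range = field_range,
    covariate_strength = covariate_strength,
    nonnative_fraction = nonnative_fraction,
    base_occupancy = base_occupancy,
    base_colonization = base_colonization,
    base_persistence = base_persistence,
    evidence_probs = evidence_probs,
    false_evidence_rate = false_evidence_rate,
    single_period_fraction = single_period_fraction,
    count_base_mean = count_base_mean,
    ringing_site_fraction = ringing_site_fraction,
    ringing_base_total = ringing_base_total,
    productivity_base_logit = productivity_base_logit
  )
  validate_sim_config(cfg)
  structure(cfg, class = "pa_sim_config")
}

fill_metric <- function(x, default) {
  out <- setNames(rep(default, length(pa_metrics())), pa_metrics())
  if (!is.null(names(x))) {
    bad <- setdiff(names(x), pa_metrics())
    assert_that(length(bad) == 0,
                paste("unknown metric name(s):", paste(bad, collapse = ", ")))
    out[names(x)] <- x
  } else {
    assert_that(length(x) == length(out), "unnamed metric vector of wrong length")
    out[] <- x
  }
  out
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_species >= 1L, "n_species must be positive")
  assert_that(cfg$n_years >= 1L, "n_years must be positive")
  assert_that(all(cfg$effect_sd >= 0), "effect SDs must be >= 0")
  assert_that(cfg$year_sd >= 0, "year_sd must be >= 0")
  assert_that(cfg$overdispersion > 0, "overdispersion (NB size) must be > 0")
  assert_that(abs(cfg$confounding_strength) <= 0.95,
              "confounding_strength must be in [-0.95, 0.95]")
  assert_that(cfg$zero_pa_fraction >= 0 && cfg$zero_pa_fraction < 1,
              "zero_pa_fraction must be in [0, 1)")
  assert_that(abs(sum(cfg$evidence_probs) - 1) < 1e-8,
              "evidence_probs must sum to 1")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys mirror the arguments of
#' [sim_config()]; absent keys take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"pa_sim_config"` object.
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rlang::check_installed("jsonlite")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    rlang::check_installed("yaml")
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  assert_that(length(bad) == 0,
              paste("unknown config key(s):", paste(bad, collapse = ", ")))
  for (nm in c("effect_mean", "effect_sd", "linkage_pop", "evidence_probs")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(sim_config, vals)
}
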