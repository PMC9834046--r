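# Per-species covariate contributions to the linear predictor, built only
# from terms the analysis models can absorb: land cover (linear), elevation
# (nonlinear, via the tensor smooth), human density (quadratic) and a shared
# mesoscale spatial field per stream (broad enough for a low-rank tensor
# smooth to capture). Returns an n_squares x n_species matrix.
covariate_eta <- function(squares, n_species, strength) {
  n <- nrow(squares)
  elev_std <- as.numeric(scale(squares$elevation))
  hd_std <- as.numeric(scale(log(squares$human_density)))
  lc <- as.matrix(squares[lc_cols()])
  f_space <- smooth_field(squares$easting, squares$northing,
                          0.4 * (diff(range(squares$easting)) + 1))
  eta <- matrix(0, n, n_species)
  for (s in seq_len(n_species)) {
    b_lc <- rnorm(ncol(lc), 0, 0.4)
    # most species are lowland: the elevation effect is negative on average,
    # which is what confounds upland-biased PA placement
    eta[, s] <- rnorm(1, -0.5, 0.45) * elev_std +
      rnorm(1, -0.2, 0.2) * elev_std^2 +
      drop(lc %*% b_lc) +
      rnorm(1, 0, 0.3) * hd_std + rnorm(1, -0.1, 0.1) * hd_std^2 +
      rnorm(1, 0, 0.5) * f_space
  }
  strength * eta
}

#' Simulate two-period atlas presence records
#'
#' Generates tetrad-level presence for two atlas periods. First-period
#' presence is Bernoulli on the logit scale (baseline + covariates + the
#' species' true occurrence slope times PA fraction); second-period presence
#' follows colonization or persistence probabilities, each with its own true
#' PA slope. Each presence record carries a breeding-evidence code
#' (possible/probable/confirmed); a small rate of spurious "possible" records
#' and a fraction of tetrads surveyed in only one period exercise the
#' downstream filters.
#'
#' @param squares Landscape tibble from [generate_landscape()].
#' @param species Species tibble from [generate_species_pool()].
#' @param config A [sim_config()] object.
#' @return A tibble with columns `square_id`, `easting`, `northing`,
#'   `species_id`, `period` (1 or 2), `present` (logical) and `evidence`
#'   (`NA` for absences).
#' @export
simulate_atlas <- function(squares, species, config) {
  withr::with_seed(stage_seed(config$seed, 303L), {
    n_sq <- nrow(squares)
    n_sp <- nrow(species)
    pop_std <- pop_size_std(species)
    eta <- covariate_eta(squares, n_sp, config$covariate_strength)
    pa <- squares$pa_all

    surveyed1 <- rep(TRUE, n_sq)
    surveyed2 <- rep(TRUE, n_sq)
    single <- runif(n_sq) < config$single_period_fraction
    p2only <- runif(n_sq) < 0.5
    surveyed1[single & p2only] <- FALSE
    surveyed2[single & !p2only] <- FALSE

    per_species <- lapply(seq_len(n_sp), function(s) {
      base <- 0.5 * pop_std[s]
      # The occurrence metric is presence in EITHER period, so its logit-PA
      # slope mixes the period-1 and colonization models. Choose the
      # period-1 slope so that, at the species' baseline, the either-period
      # outcome has exactly the species' true occurrence slope:
      # d logit(pu)/d pa = beta_occ with pu = q1 + (1-q1)*pcol.
      q1 <- mean(plogis(qlogis(config$base_occupancy) + base + eta[, s]))
      pc <- mean(plogis(qlogis(config$base_colonization) + base + eta[, s]))
      pu <- q1 + (1 - q1) * pc
      beta1 <- (species$beta_occurrence[s] * pu * (1 - pu) -
                  (1 - q1) * pc * (1 - pc) * species$beta_colonization[s]) /
        (q1 * (1 - q1) * (1 - pc))
      p1 <- plogis(qlogis(config$base_occupancy) + base + eta[, s] +
                     beta1 * pa)
      pres1 <- rbinom(n_sq, 1, p1) == 1
      p_col <- plogis(qlogis(config$base_colonization) + base + eta[, s] +
                        species$beta_colonization[s] * pa)
      p_per <- plogis(qlogis(config$base_persistence) + base + eta[, s] +
                        species$beta_persistence[s] * pa)
      pres2 <- rbinom(n_sq, 1, ifelse(pres1, p_per, p_col)) == 1
      tibble::tibble(
        square_id = rep(squares$square_id, 2),
        easting = rep(squares$easting, 2),
        northing = rep(squares$northing, 2),
        species_id = species$species_id[s],
        period = rep(1:2, each = n_sq),
        present = c(pres1, pres2),
        surveyed = c(surveyed1, surveyed2)
      )
    })
    atlas <- dplyr::bind_rows(per_species) |>
      dplyr::filter(.data$surveyed) |>
      dplyr::select(-"surveyed")

    ev <- config$evidence_probs
    n_rec <- nrow(atlas)
    code <- sample(names(ev), n_rec, replace = TRUE, prob = ev)
    spurious <- !atlas$present & runif(n_rec) < config$false_evidence_rate
    atlas$present <- atlas$present | spurious
    atlas$evidence <- dplyr::if_else(spurious, "possible",
                                     dplyr::if_else(atlas$present, code,
                                                    NA_character_))
    atlas
  })
}

#' Simulate annual two-visit count records
#'
#' Counts follow a negative binomial (mean/size parameterization; variance =
#' mu + mu^2/size) with log-mean built from covariates, a quadratic year
#' trend, a year random intercept shared across species, the species' true
#' abundance and abundance-trend PA slopes, and a `log(n_transect_squares)`
#' effort offset. The recorded maximum of the two visits equals the drawn
#' count; the other visit is a binomial thinning of it.
#'
#' @inheritParams simulate_atlas
#' @return A tibble with `square_id`, `species_id`, `year` (1..n_years),
#'   `visit1`, `visit2` and `count` (the visit maximum).
#' @export
simulate_counts <- function(squares, species, config) {
  assert_that(config$n_years >= 3L,
              "n_years < 3: abundance trend unidentifiable")
  withr::with_seed(stage_seed(config$seed, 404L), {
    n_sq <- nrow(squares)
    n_sp <- nrow(species)
    n_yr <- config$n_years
    pop_std <- pop_size_std(species)
    eta <- covariate_eta(squares, n_sp, config$covariate_strength)
    pa <- squares$pa_all
    offset_log <- log(squares$n_transect_squares)
    u_year <- rnorm(n_yr, 0, config$year_sd)
    yrc <- seq_len(n_yr) - (n_yr + 1) / 2

    per_species <- lapply(seq_len(n_sp), function(s) {
      b1 <- rnorm(1, 0, 0.02)
      b2 <- rnorm(1, 0, 0.004)
      base <- log(config$count_base_mean) + 0.8 * pop_std[s]
      lp <- outer(0.5 * eta[, s] + base + species$beta_abundance[s] * pa +
                    offset_log,
                  b1 * yrc + b2 * yrc^2 + u_year, "+") +
        outer(species$beta_abundance_trend[s] * pa, yrc)
      mu <- exp(pmin(lp, 10))
      count <- rnbinom(length(mu), mu = as.numeric(mu),
                       size = config$overdispersion)
      other <- rbinom(length(count), count, 0.8)
      first_is_max <- runif(length(count)) < 0.5
      tibble::tibble(
        square_id = rep(squares$square_id, n_yr),
        species_id = species$species_id[s],
        year = rep(seq_len(n_yr), each = n_sq),
        visit1 = ifelse(first_is_max, count, other),
        visit2 = ifelse(first_is_max, other, count),
        count = count
      )
    })
    dplyr::bind_rows(per_species)
  })
}

#' Simulate constant-effort ringing (capture) records
#'
#' A subset of squares hosts ringing sites. Per site-year-species, total
#' captures are Poisson and the number of juveniles is binomial with
#' logit-probability built from covariates, the species' true productivity
#' and productivity-trend PA slopes. Early/late visit counts are recorded so
#' the visit-completeness filter can be exercised.
#'
#' @inheritParams simulate_atlas
#' @return A tibble with `site_id` (a square id), `species_id`, `year`,
#'   `n_juv`, `n_ad`, `n_early_visits`, `n_late_visits`.
#' @export
simulate_ringing <- function(squares, species, config) {
  withr::with_seed(stage_seed(config$seed, 505L), {
    n_sp <- nrow(species)
    n_yr <- config$n_years
    n_sites <- max(3L, round(config$ringing_site_fraction * nrow(squares)))
    sites <- squares[sample.int(nrow(squares), n_sites), ]
    pop_std <- pop_size_std(species)
    eta <- covariate_eta(sites, n_sp, config$covariate_strength)
    pa <- sites$pa_all
    yrc <- seq_len(n_yr) - (n_yr + 1) / 2

    visits <- function(k) sample(2:6, k, replace = TRUE,
                                 prob = c(0.05, 0.10, 0.25, 0.32, 0.28))
    per_species <- lapply(seq_len(n_sp), function(s) {
      lambda <- exp(pmin(log(config$ringing_base_total) + 0.5 * pop_std[s] +
                           0.3 * eta[, s], 8))
      grid <- tidyr::expand_grid(site = seq_len(n_sites),
                                 year = seq_len(n_yr))
      total <- rpois(nrow(grid), lambda[grid$site])
      p_juv <- plogis(config$productivity_base_logit + 0.3 * eta[grid$site, s] +
                        species$beta_productivity[s] * pa[grid$site] +
                        species$beta_productivity_trend[s] * pa[grid$site] *
                          yrc[grid$year])
      n_juv <- rbinom(nrow(grid), total, p_juv)
      tibble::tibble(
        site_id = sites$square_id[grid$site],
        species_id = species$species_id[s],
        year = grid$year,
        n_juv = n_juv,
        n_ad = total - n_juv,
        n_early_visits = visits(nrow(grid)),
        n_late_visits = visits(nrow(grid))
      )
    })
    dplyr::bind_rows(per_species)
  })
}

#' Simulate a full multi-stream survey data set
#'
#' Convenience wrapper running [generate_landscape()],
#' [generate_species_pool()], [simulate_atlas()], [simulate_counts()] and
#' [simulate_ringing()] under one configuration.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `config`, `squares`, `species`, `phylogeny`,
#'   `atlas`, `counts`, `ringing` and `truth` (long species-by-metric true
#'   slopes).
#' @export
#' @examples
#' sim <- simulate_survey_data(sim_config(n_squares = 50, n_species = 4,
#'                                        n_years = 4, seed = 1))
#' names(sim)
simulate_survey_data <- function(config) {
  squares <- generate_landscape(config)
  pool <- generate_species_pool(config)
  list(
    config = config,
    squares = squares,
    species = pool$species,
    phylogeny = pool$phylogeny,
    atlas = simulate_atlas(squares, pool$species, config),
    counts = simulate_counts(squares, pool$species, config),
    ringing = simulate_ringing(squares, pool$species, config),
    truth = truth_table(pool$species)
  )
}

#' Write a simulated data set to delimited-text files
#'
#' Writes `squares.csv`, `species.csv`, `atlas.csv`, `counts.csv`,
#' `ringing.csv`, `truth.csv` (UTF-8, comma-delimited, header row) and
#' `phylogeny.nwk` (newick) into `dir`.
#'
#' @param sim Output of [simulate_survey_data()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$squares, file.path(dir, "squares.csv"))
  readr::write_csv(sim$species, file.path(dir, "species.csv"))
  readr::write_csv(sim$atlas, file.path(dir, "atlas.csv"))
  readr::write_csv(sim$counts, file.path(dir, "counts.csv"))
  readr::write_csv(sim$ringing, file.path(dir, "ringing.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  ape::write.tree(sim$phylogeny, file.path(dir, "phylogeny.nwk"))
  invisible(dir)
}
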