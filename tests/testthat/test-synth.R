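test_that("landscape generation is deterministic and respects invariants", {
  cfg <- tiny_config(seed = 5)
  sq1 <- generate_landscape(cfg)
  sq2 <- generate_landscape(cfg)
  expect_identical(sq1, sq2)

  expect_true(all(abs(rowSums(sq1[lc_cols()]) - 1) < 1e-9))
  expect_true(all(sq1[lc_cols()] >= 0))
  expect_true(all(sq1$pa_all >= pmax(sq1$pa_sssi, sq1$pa_spa, sq1$pa_sac)))
  expect_true(all(is.finite(sq1$elevation)))
  expect_true(all(sq1$n_transect_squares %in% c(1L, 2L)))
  expect_true(all(sq1$pa_all >= 0 & sq1$pa_all <= 1))

  expect_error(generate_landscape(tiny_config(n_squares = 9)),
               "n_squares < 10")
})

test_that("PA placement confounding tracks the configured strength", {
  sq0 <- generate_landscape(sim_config(n_squares = 2000, n_species = 3,
                                       n_years = 3, seed = 21,
                                       confounding_strength = 0))
  expect_lt(abs(cor(sq0$pa_all, sq0$elevation)), 0.1)

  sq6 <- generate_landscape(sim_config(n_squares = 2000, n_species = 3,
                                       n_years = 3, seed = 21,
                                       confounding_strength = 0.6))
  r <- cor(sq6$pa_all, sq6$elevation)
  expect_gt(r, 0.45)
  expect_lt(r, 0.75)
  expect_lt(cor(sq6$pa_all, log(sq6$human_density)), -0.45)

  frac0 <- mean(sq6$pa_all == 0)
  expect_gt(frac0, 0.25)
  expect_lt(frac0, 0.35)
})

test_that("species pool links true effects to population size as configured", {
  cfg <- sim_config(n_squares = 100, n_species = 200, n_years = 5, seed = 3,
                    linkage_pop = c(occurrence = -0.3))
  pool <- generate_species_pool(cfg)
  expect_equal(ape::Ntip(pool$phylogeny), 200)
  expect_setequal(pool$phylogeny$tip.label, pool$species$species_id)

  z <- scale(log(pool$species$pop_size_early))
  sl <- coef(lm(pool$species$beta_occurrence ~ z))[2]
  expect_gt(sl, -0.45)
  expect_lt(sl, -0.15)

  # zero linkage: slope within 2 Monte-Carlo SEs of zero
  cfg0 <- sim_config(n_squares = 100, n_species = 200, n_years = 5, seed = 3,
                     linkage_pop = c(occurrence = 0))
  pool0 <- generate_species_pool(cfg0)
  z0 <- scale(log(pool0$species$pop_size_early))
  f0 <- summary(lm(pool0$species$beta_occurrence ~ z0))$coefficients
  expect_lt(abs(f0[2, 1]), 2 * f0[2, 2])

  expect_error(generate_species_pool(tiny_config(n_species = 2)),
               "n_species < 3")
})

test_that("species traits and listings are well formed", {
  pool <- generate_species_pool(sim_config(n_squares = 50, n_species = 100,
                                           n_years = 3, seed = 9))
  sp <- pool$species
  expect_true(all(sp$mass > 0))
  expect_true(all(sp$pop_size_early > 0 & sp$pop_size_late > 0))
  expect_true(all(sp$detectability > 0 & sp$detectability <= 1))
  expect_true(all(sp$ssi >= 0))
  expect_true(all(sp$bocc %in% c("green", "amber", "red")))
  expect_true(ape::is.ultrametric(pool$phylogeny, tol = 1e-6))
})

test_that("atlas saturation, flat-null occupancy and persistence odds ratio", {
  # saturating colonization intercept: nearly every eligible tetrad colonized
  cfg_sat <- sim_config(n_squares = 2000, n_species = 3, n_years = 3,
                        seed = 2, base_colonization = plogis(10),
                        covariate_strength = 0, single_period_fraction = 0,
                        false_evidence_rate = 0,
                        effect_mean = setNames(rep(0, 7), pa_metrics()),
                        effect_sd = setNames(rep(0, 7), pa_metrics()),
                        linkage_pop = setNames(rep(0, 7), pa_metrics()),
                        linkage_change = 0)
  sq <- generate_landscape(cfg_sat)
  pool <- generate_species_pool(cfg_sat)
  pool$species$beta_occurrence <- 0  # keep period-1 free of PA signal
  at <- simulate_atlas(sq, pool$species, cfg_sat)
  wide <- tidyr::pivot_wider(
    dplyr::select(at, "square_id", "species_id", "period", "present"),
    names_from = "period", values_from = "present", names_prefix = "p")
  eligible <- dplyr::filter(wide, !p1)
  expect_gt(mean(eligible$p2), 0.99)

  # flat covariates, all slopes zero, baseline 0.5: occupancy ~ 0.5
  cfg_null <- null_config(seed = 4, n_squares = 2000, n_species = 3,
                          covariate_strength = 0, base_occupancy = 0.5,
                          false_evidence_rate = 0)
  sq2 <- generate_landscape(cfg_null)
  pool2 <- generate_species_pool(cfg_null)
  pool2$species$pop_size_early <- rep(2e5, 3)  # flat baselines
  at2 <- simulate_atlas(sq2, pool2$species, cfg_null)
  occ1 <- mean(dplyr::filter(at2, period == 1)$present)
  expect_lt(abs(occ1 - 0.5), 0.02)

  # binary-PA persistence odds ratio ~ exp(1)
  cfg_or <- null_config(seed = 6, n_squares = 5000, n_species = 3,
                        covariate_strength = 0, single_period_fraction = 0,
                        false_evidence_rate = 0)
  sq3 <- generate_landscape(cfg_or)
  sq3$pa_all <- rep(c(0, 1), length.out = nrow(sq3))
  pool3 <- generate_species_pool(cfg_or)
  pool3$species$pop_size_early <- rep(2e5, 3)
  pool3$species$beta_persistence <- 1
  at3 <- simulate_atlas(sq3, pool3$species, cfg_or)
  wide3 <- tidyr::pivot_wider(
    dplyr::select(at3, "square_id", "species_id", "period", "present"),
    names_from = "period", values_from = "present", names_prefix = "p") |>
    dplyr::inner_join(dplyr::select(sq3, "square_id", "pa_all"),
                      by = "square_id") |>
    dplyr::filter(p1)
  tab <- table(wide3$pa_all, wide3$p2)
  or <- (tab["1", "TRUE"] / tab["1", "FALSE"]) /
    (tab["0", "TRUE"] / tab["0", "FALSE"])
  expect_gt(or, exp(1) * 0.8)
  expect_lt(or, exp(1) * 1.25)
})

test_that("count stream honors Poisson limit, trend slope and effort offset", {
  base_null <- function(seed, ...) {
    null_config(seed = seed, n_squares = 2000, n_species = 3, n_years = 9,
                covariate_strength = 0, year_sd = 0, ...)
  }
  # Poisson limit: huge size parameter, intercept log(5)
  cfg <- base_null(8, overdispersion = 1e8, count_base_mean = 5)
  sq <- generate_landscape(cfg)
  sq$n_transect_squares <- 1L
  pool <- generate_species_pool(cfg)
  pool$species$pop_size_early <- rep(2e5, 3)
  cts <- simulate_counts(sq, pool$species, cfg)
  # condition on one species-year to dodge the species year-curve draws
  one <- dplyr::filter(cts, species_id == "sp001", year == 5)
  expect_lt(abs(mean(one$count) - 5), 0.35)
  expect_lt(abs(var(one$count) / mean(one$count) - 1), 0.15)

  # trend: beta_tr = 0.05 difference in log-mean yearly slopes, pa 1 vs 0
  cfg2 <- base_null(9, overdispersion = 5)
  sq2 <- generate_landscape(cfg2)
  sq2$pa_all <- rep(c(0, 1), length.out = nrow(sq2))
  sq2$n_transect_squares <- 1L
  pool2 <- generate_species_pool(cfg2)
  pool2$species$beta_abundance_trend <- 0.05
  cts2 <- simulate_counts(sq2, pool2$species, cfg2)
  sl <- cts2 |>
    dplyr::inner_join(dplyr::select(sq2, "square_id", "pa_all"),
                      by = "square_id") |>
    dplyr::group_by(.data$pa_all, .data$year) |>
    dplyr::summarise(lm_mean = log(mean(count)), .groups = "drop") |>
    dplyr::group_by(.data$pa_all) |>
    dplyr::summarise(slope = coef(lm(lm_mean ~ year))[2]) |>
    dplyr::arrange(.data$pa_all)
  expect_lt(abs(diff(sl$slope) - 0.05), 0.02)

  # offset: doubled-transect squares have ~2x the counts
  cfg3 <- base_null(10)
  sq3 <- generate_landscape(cfg3)
  sq3$n_transect_squares <- rep(c(1L, 2L), length.out = nrow(sq3))
  pool3 <- generate_species_pool(cfg3)
  cts3 <- simulate_counts(sq3, pool3$species, cfg3) |>
    dplyr::inner_join(dplyr::select(sq3, "square_id", "n_transect_squares"),
                      by = "square_id") |>
    dplyr::group_by(.data$n_transect_squares) |>
    dplyr::summarise(m = mean(count))
  ratio <- cts3$m[cts3$n_transect_squares == 2] /
    cts3$m[cts3$n_transect_squares == 1]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)

  expect_error(simulate_counts(sq3, pool3$species,
                               tiny_config(n_years = 2)),
               "n_years < 3")
})

test_that("ringing stream gives the configured juvenile log-odds contrast", {
  cfg <- null_config(seed = 12, n_squares = 3000, n_species = 3, n_years = 8,
                     covariate_strength = 0, productivity_base_logit = 0,
                     ringing_site_fraction = 1)
  sq <- generate_landscape(cfg)
  sq$pa_all <- rep(c(0, 1), length.out = nrow(sq))
  pool <- generate_species_pool(cfg)

  # intercept 0, no slopes: pooled juvenile proportion ~ 0.5
  rg0 <- simulate_ringing(sq, pool$species, cfg)
  expect_lt(abs(sum(rg0$n_juv) / sum(rg0$n_juv + rg0$n_ad) - 0.5), 0.01)

  # beta_prod = 0.8: empirical logit difference between strata ~ 0.8
  pool$species$beta_productivity <- 0.8
  rg <- simulate_ringing(sq, pool$species, cfg) |>
    dplyr::inner_join(dplyr::select(sq, site_id = "square_id", "pa_all"),
                      by = "site_id") |>
    dplyr::group_by(.data$pa_all) |>
    dplyr::summarise(lo = qlogis(sum(n_juv) / sum(n_juv + n_ad))) |>
    dplyr::arrange(.data$pa_all)
  expect_lt(abs(diff(rg$lo) - 0.8), 0.05)

  # determinism
  rg2 <- simulate_ringing(sq, pool$species, cfg)
  expect_identical(rg, dplyr::inner_join(
    rg2, dplyr::select(sq, site_id = "square_id", "pa_all"),
    by = "site_id") |>
      dplyr::group_by(.data$pa_all) |>
      dplyr::summarise(lo = qlogis(sum(n_juv) / sum(n_juv + n_ad))) |>
      dplyr::arrange(.data$pa_all))
})

test_that("every stream is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 77)
  s1 <- simulate_survey_data(cfg)
  s2 <- simulate_survey_data(cfg)
  expect_identical(s1$squares, s2$squares)
  expect_identical(s1$species, s2$species)
  expect_identical(s1$atlas, s2$atlas)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$ringing, s2$ringing)
  expect_identical(ape::write.tree(s1$phylogeny),
                   ape::write.tree(s2$phylogeny))
})

test_that("marginal rates respond to true slopes in the right direction", {
  hit <- 0L
  for (s in 1:10) {
    cfg <- null_config(seed = 100 + s, n_squares = 800, n_species = 3,
                       covariate_strength = 0, false_evidence_rate = 0)
    sq <- generate_landscape(cfg)
    pool <- generate_species_pool(cfg)
    pool$species$beta_occurrence <- 1.5
    pool$species$beta_colonization <- 0
    at <- simulate_atlas(sq, pool$species, cfg)
    p1 <- dplyr::filter(at, period == 1) |>
      dplyr::inner_join(dplyr::select(sq, "square_id", "pa_all"),
                        by = "square_id")
    hi <- mean(p1$present[p1$pa_all > 0.5])
    lo <- mean(p1$present[p1$pa_all == 0])
    if (hi > lo) hit <- hit + 1L
  }
  expect_gte(hit, 9L)
})

test_that("simulation files round-trip through the writers", {
  dir <- withr::local_tempdir()
  sim <- simulate_survey_data(tiny_config(seed = 15))
  write_simulation(sim, dir)
  expect_setequal(list.files(dir),
                  c("squares.csv", "species.csv", "atlas.csv", "counts.csv",
                    "ringing.csv", "truth.csv", "phylogeny.nwk"))
  sq <- readr::read_csv(file.path(dir, "squares.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(sq), nrow(sim$squares))
  tree <- ape::read.tree(file.path(dir, "phylogeny.nwk"))
  expect_setequal(tree$tip.label, sim$species$species_id)
})
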