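# Small shared fixtures, all generated in code.

tiny_config <- function(seed = 1, n_squares = 120, n_species = 5,
                        n_years = 5, ...) {
  sim_config(n_squares = n_squares, n_species = n_species, n_years = n_years,
             seed = seed, ...)
}

# a null configuration: every true PA slope is exactly zero
null_config <- function(seed = 1, n_squares = 500, n_species = 25,
                        n_years = 5, ...) {
  zero <- setNames(rep(0, length(pa_metrics())), pa_metrics())
  sim_config(n_squares = n_squares, n_species = n_species, n_years = n_years,
             seed = seed, effect_mean = zero, effect_sd = zero,
             linkage_pop = zero, linkage_change = 0, ...)
}

# hand-built atlas records: one row per tetrad-period-species
atlas_row <- function(square_id, e, n, period, present, evidence = NA,
                      species_id = "spA") {
  tibble::tibble(square_id = square_id, easting = e, northing = n,
                 species_id = species_id, period = period,
                 present = present, evidence = evidence)
}

# minimal squares table with controllable pa and unstructured covariates
flat_squares <- function(n, pa = rep(0, n), seed = 99) {
  withr::with_seed(seed, {
    lc <- matrix(rexp(10 * n), n, 10, dimnames = list(NULL, lc_cols()))
    lc <- lc / rowSums(lc)
    dplyr::bind_cols(
      tibble::tibble(
        square_id = sprintf("sq%05d", seq_len(n)),
        easting = runif(n, 0, 30), northing = runif(n, 0, 30),
        elevation = runif(n, 0, 400),
        human_density = exp(rnorm(n, 4, 0.5))
      ),
      tibble::as_tibble(lc),
      tibble::tibble(pa_all = pa, pa_sssi = pa / 2, pa_spa = pa / 2,
                     pa_sac = pa / 2, n_transect_squares = 1L)
    )
  })
}
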