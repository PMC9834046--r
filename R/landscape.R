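# Smooth Gaussian-kernel random field over planar coordinates, standardized to
# mean 0 / sd 1. Used for every spatially autocorrelated covariate.
smooth_field <- function(easting, northing, range_km, n_centres = NULL) {
  if (is.null(n_centres)) {
    area <- (diff(range(easting)) + 1) * (diff(range(northing)) + 1)
    n_centres <- min(400L, max(40L, ceiling(3 * area / range_km^2)))
  }
  ctr_e <- runif(n_centres, min(easting), max(easting))
  ctr_n <- runif(n_centres, min(northing), max(northing))
  w <- rnorm(n_centres)
  d2 <- outer(easting, ctr_e, "-")^2 + outer(northing, ctr_n, "-")^2
  f <- exp(-d2 / (2 * range_km^2)) %*% w
  as.numeric(scale(f))
}

# residual of f after projecting out columns of basis (plus intercept),
# standardized
orthogonalize <- function(f, basis) {
  r <- stats::lm.fit(cbind(1, basis), f)$residuals
  as.numeric(scale(r))
}

#' Generate a synthetic monitoring landscape
#'
#' Lays `n_squares` 1-km squares on a planar grid and draws spatially smooth
#' covariates: elevation, mesoscale human population density, ten land-cover
#' proportions (summing to 1) and protected-area coverage fractions for the
#' four designations (`ALL`, `SSSI`, `SPA`, `SAC`, the last three nested
#' within `ALL`). PA placement is confounded: coverage rises with elevation
#' and falls with human density at approximately
#' `config$confounding_strength`, and about `config$zero_pa_fraction` of
#' squares have exactly zero coverage so a matched design has true controls.
#' A small set of high-elevation squares gets `n_transect_squares = 2`,
#' emulating the doubled transect effort used in poorly covered uplands.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per square: `square_id`, `easting`,
#'   `northing` (km), `elevation` (m), `human_density` (ind/km^2), `lc_*`
#'   proportions, `pa_all`, `pa_sssi`, `pa_spa`, `pa_sac`,
#'   `n_transect_squares`.
#' @export
#' @examples
#' sq <- generate_landscape(sim_config(n_squares = 100, n_species = 5,
#'                                     n_years = 5, seed = 1))
#' cor(sq$pa_all, sq$elevation)
generate_landscape <- function(config) {
  assert_that(inherits(config, "pa_sim_config"), "config must be a pa_sim_config")
  assert_that(config$n_squares >= 10L,
              "n_squares < 10: landscape too degenerate to analyse")
  withr::with_seed(stage_seed(config$seed, 101L), {
    n <- config$n_squares
    side <- ceiling(sqrt(n))
    easting <- (seq_len(n) - 1L) %% side
    northing <- (seq_len(n) - 1L) %/% side
    rng <- config$field_range

    # Smooth fields have few effective degrees of freedom, so independent
    # draws can be strongly sample-correlated; residualize the later fields
    # on the earlier ones so the confounding loadings below are exact
    # in-sample.
    f_elev <- smooth_field(easting, northing, rng)
    f_hum <- orthogonalize(smooth_field(easting, northing, rng), f_elev)
    # the PA-specific placement field is finer-scaled than the covariate
    # fields: site selection varies locally, which also keeps identifiable
    # within-region coverage variation after spatial adjustment
    f_pa <- orthogonalize(smooth_field(easting, northing, rng / 2),
                          cbind(f_elev, f_hum, f_elev^2, f_hum^2,
                                f_elev * f_hum))

    elevation <- 600 * plogis(1.2 * f_elev)
    log_hd <- log(150) + 0.9 * (-f_elev + f_hum) / sqrt(2)
    human_density <- exp(log_hd)

    # PA latent: loadings chosen so cor(latent, f_elev) = rho and
    # cor(latent, log_hd) = -rho; kappa compensates the attenuation of the
    # thresholded logistic transform below.
    rho <- config$confounding_strength
    kappa <- 1.05
    c1 <- min(0.92, kappa * rho)
    c2 <- c1 * (1 - sqrt(2))
    c3 <- sqrt(max(0.01, 1 - c1^2 - c2^2))
    z_pa <- c1 * f_elev + c2 * f_hum + c3 * f_pa
    thr <- quantile(z_pa, config$zero_pa_fraction)
    pa_all <- ifelse(z_pa <= thr, 0, 2 * (plogis(1.2 * (z_pa - thr)) - 0.5))

    shares <- lapply(1:3, function(i) {
      plogis(-0.5 + 0.9 * smooth_field(easting, northing, rng))
    })

    # land cover: softmax of latents anchored at UK aggregate-class shares
    base_pct <- c(7.4, 4.9, 24.7, 32.7, 8.0, 10.4, 0.7, 1.2, 2.1, 8.0)
    b_elev <- c(-0.2, 0.5, -1.0, -0.5, 0.3, 1.8, 0, 0, 0, -0.5)
    b_hum <- c(0, -0.2, 0.3, 0, -0.2, -0.5, 0, 0, 0, 1.5)
    hum_std <- as.numeric(scale(log_hd))
    lat <- vapply(seq_along(base_pct), function(k) {
      log(base_pct[k]) + b_elev[k] * f_elev + b_hum[k] * hum_std +
        0.6 * smooth_field(easting, northing, rng)
    }, numeric(n))
    lc <- exp(lat)
    lc <- lc / rowSums(lc)
    colnames(lc) <- lc_cols()

    upland <- elevation > quantile(elevation, 0.93)
    n_transect <- ifelse(upland & runif(n) < 0.7, 2L, 1L)

    dplyr::bind_cols(
      tibble::tibble(
        square_id = sprintf("sq%05d", seq_len(n)),
        easting = as.numeric(easting),
        northing = as.numeric(northing),
        elevation = elevation,
        human_density = human_density
      ),
      tibble::as_tibble(lc),
      tibble::tibble(
        pa_all = pa_all,
        pa_sssi = pa_all * shares[[1]],
        pa_spa = pa_all * shares[[2]],
        pa_sac = pa_all * shares[[3]],
        n_transect_squares = n_transect
      )
    )
  })
}
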