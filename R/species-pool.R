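# Brownian-motion trait on a tree plus independent noise, standardized.
# C is the tip covariance of the tree scaled to unit diagonal.
bm_trait <- function(chol_C, bm_weight = 0.7) {
  n <- nrow(chol_C)
  bm <- as.numeric(t(chol_C) %*% rnorm(n))
  as.numeric(scale(bm_weight * bm + sqrt(1 - bm_weight^2) * rnorm(n)))
}

#' Generate a species pool and its phylogeny
#'
#' Draws an ultrametric coalescent phylogeny, evolves species traits on it
#' under Brownian motion plus independent noise, and assigns each species
#' ground-truth PA slopes for the seven population metrics. True slopes are
#' linked to traits: by default the occurrence/colonization/persistence/
#' abundance slopes decrease with standardized log population size (rarer
#' species benefit more) and the abundance-trend slope decreases with
#' standardized log population change (declining species have more positive
#' trends in PAs), per `config$linkage_pop` and `config$linkage_change`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `species` (tibble: identifiers, traits, conservation
#'   listings, detectability, native flag and `beta_<metric>` truth columns)
#'   and `phylogeny` (an `ape::phylo` whose tip labels are the species ids).
#' @export
#' @examples
#' pool <- generate_species_pool(sim_config(n_squares = 100, n_species = 8,
#'                                          n_years = 5, seed = 1))
#' pool$species$species_id
#' ape::Ntip(pool$phylogeny)
generate_species_pool <- function(config) {
  assert_that(inherits(config, "pa_sim_config"), "config must be a pa_sim_config")
  assert_that(config$n_species >= 3L,
              "n_species < 3: species pool too small")
  withr::with_seed(stage_seed(config$seed, 202L), {
    n <- config$n_species
    ids <- sprintf("sp%03d", seq_len(n))
    tree <- ape::rcoal(n, tip.label = ids)
    C <- ape::vcv(tree)
    C <- C / max(diag(C))
    cC <- chol(C + diag(1e-10, n))

    mass_std <- bm_trait(cC)
    log_mass <- log(20) + 1.2 * mass_std               # grams, median ~20
    pop_std <- as.numeric(scale(2.0 * bm_trait(cC) - 0.5 * mass_std))
    log_pop_early <- log(2e5) + 1.8 * pop_std           # individuals
    change_std <- bm_trait(cC, bm_weight = 0.5)
    log_pop_change <- 0.6 * change_std                  # log ratio late/early
    pop_size_early <- exp(log_pop_early)
    pop_size_late <- exp(log_pop_early + log_pop_change)

    ssi <- exp(0.4 * bm_trait(cC))                      # lognormal around 1
    sti <- 12 + 2 * bm_trait(cC)                        # degrees C

    habitats <- c("farmland", "woodland", "wetland", "upland", "urban",
                  "coastal", "generalist")
    hab_scores <- vapply(habitats, function(h) bm_trait(cC, 0.6), numeric(n))
    habitat <- habitats[max.col(hab_scores)]

    # conservation listings: red/amber species are declining and/or rare
    concern <- -change_std - 0.5 * pop_std + 0.5 * rnorm(n)
    bocc <- cut(concern, quantile(concern, c(0, 0.40, 0.75, 1)),
                labels = c("green", "amber", "red"), include.lowest = TRUE)
    schedule1 <- runif(n) < plogis(-1.5 - 1.0 * pop_std)
    annex1 <- runif(n) < plogis(-1.5 - 0.8 * pop_std + 0.5 * (bocc == "red"))

    detectability <- plogis(rnorm(n, 0.5, 0.8))
    native <- runif(n) >= config$nonnative_fraction

    truths <- vapply(pa_metrics(), function(m) {
      link <- if (m == "abundance_trend") {
        config$linkage_pop[[m]] * pop_std + config$linkage_change * change_std
      } else {
        config$linkage_pop[[m]] * pop_std
      }
      config$effect_mean[[m]] + link + config$effect_sd[[m]] * rnorm(n)
    }, numeric(n))
    colnames(truths) <- paste0("beta_", pa_metrics())

    species <- dplyr::bind_cols(
      tibble::tibble(
        species_id = ids,
        mass = exp(log_mass),
        pop_size_early = pop_size_early,
        pop_size_late = pop_size_late,
        pop_change = pop_size_late / pop_size_early,
        ssi = ssi,
        sti = sti,
        habitat = habitat,
        bocc = as.character(bocc),
        schedule1 = schedule1,
        annex1 = annex1,
        detectability = detectability,
        native = native
      ),
      tibble::as_tibble(truths)
    )
    list(species = species, phylogeny = tree)
  })
}

# standardized log population size, used by all simulators for baselines;
# a pool with equal population sizes standardizes to zeros
pop_size_std <- function(species) {
  v <- log(species$pop_size_early)
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  as.numeric(scale(v))
}

#' Long ground-truth slope table
#'
#' Reshapes the `beta_<metric>` truth columns of a synthetic species pool
#' into a long species-by-metric table, the form used by recovery harnesses
#' and written to `truth.csv`.
#'
#' @param species Species tibble from [generate_species_pool()].
#' @return A tibble with `species_id`, `metric`, `true_beta`.
#' @export
truth_table <- function(species) {
  species |>
    dplyr::select("species_id", dplyr::starts_with("beta_")) |>
    tidyr::pivot_longer(dplyr::starts_with("beta_"),
                        names_to = "metric", values_to = "true_beta",
                        names_prefix = "beta_")
}
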