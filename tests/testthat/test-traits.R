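test_that("Brownian covariance matches path-length arithmetic", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  Cs <- brownian_covariance(star)
  expect_equal(unclass(Cs), diag(3), ignore_attr = TRUE)

  cherry <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  Cc <- brownian_covariance(cherry)
  expect_equal(Cc["A", "B"], 0.5)
  expect_equal(Cc["A", "C"], 0)
  expect_equal(diag(unclass(Cc)), c(A = 1, B = 1, C = 1))

  half <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  Ch <- brownian_covariance(half)
  expect_equal(Ch["A", "B"], 0.5)

  nonultra <- ape::read.tree(text = "((A:1,B:2):1,C:4);")
  expect_warning(Cn <- brownian_covariance(nonultra), "ultrametric")
  expect_equal(diag(unclass(Cn)), c(A = 1, B = 1, C = 1))
})

test_that("GLS with a star tree and equal weights equals OLS", {
  withr::with_seed(20, {
    n <- 60
    dat <- tibble::tibble(
      species_id = sprintf("t%02d", 1:n),
      x = rnorm(n), z = rnorm(n),
      beta = 1 + 0.5 * rnorm(n) + 0.3 * rnorm(n)
    )
    dat$beta <- 0.7 + 0.4 * dat$x - 0.2 * dat$z + rnorm(n, 0, 0.5)
  })
  star <- ape::stree(n, tip.label = dat$species_id)
  star$edge.length <- rep(1, nrow(star$edge))
  C <- brownian_covariance(star)
  fit <- fit_phylo_regression(dat, beta ~ x + z, C)
  ols <- lm(beta ~ x + z, dat)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-8)
})

test_that("GLS coefficients are equivariant under predictor rescaling", {
  withr::with_seed(21, {
    n <- 40
    tree <- ape::rcoal(n, tip.label = sprintf("t%02d", 1:n))
    C <- brownian_covariance(tree)
    bm <- as.numeric(t(chol(unclass(C))) %*% rnorm(n))
    dat <- tibble::tibble(species_id = sprintf("t%02d", 1:n),
                          x = rnorm(n),
                          beta = 1 + 0.5 * rnorm(n) + bm)
  })
  f1 <- fit_phylo_regression(dat, beta ~ x, C)
  dat2 <- dplyr::mutate(dat, x = (x - 3) / 7)
  f2 <- fit_phylo_regression(dat2, beta ~ x, C)
  sl1 <- f1$coefficients$estimate[f1$coefficients$term == "x"]
  sl2 <- f2$coefficients$estimate[f2$coefficients$term == "x"]
  expect_equal(sl1, sl2 / 7, tolerance = 1e-6)
})

test_that("GLS agrees with metafor's phylogenetic meta-regression", {
  skip_if_not_installed("metafor")
  withr::with_seed(22, {
    n <- 50
    ids <- sprintf("t%02d", 1:n)
    tree <- ape::rcoal(n, tip.label = ids)
    C <- brownian_covariance(tree)
    bm <- as.numeric(t(chol(unclass(C) + diag(1e-10, n))) %*% rnorm(n)) * 0.6
    dat <- tibble::tibble(
      species_id = ids, x = rnorm(n),
      vi = runif(n, 0.02, 0.3)
    )
    dat$beta <- 0.5 - 0.4 * dat$x + bm + rnorm(n, 0, 0.3) +
      rnorm(n, 0, sqrt(dat$vi))
  })
  fit <- fit_phylo_regression(dat, beta ~ x, C, vi = dat$vi)
  rm <- metafor::rma.mv(beta ~ x, V = dat$vi,
                        random = list(~ 1 | species_id, ~ 1 | id2),
                        R = list(species_id = unclass(C)),
                        data = dplyr::mutate(dat, id2 = species_id),
                        method = "REML")
  expect_equal(fit$coefficients$estimate, as.numeric(rm$beta),
               tolerance = 0.02)
  expect_equal(fit$coefficients$se, as.numeric(rm$se), tolerance = 0.05)
})

test_that("MCMC engine is seed-reproducible and agrees with GLS", {
  withr::with_seed(23, {
    n <- 80
    ids <- sprintf("t%02d", 1:n)
    tree <- ape::rcoal(n, tip.label = ids)
    C <- brownian_covariance(tree)
    bm <- as.numeric(t(chol(unclass(C) + diag(1e-10, n))) %*% rnorm(n)) * 0.5
    dat <- tibble::tibble(species_id = ids, x = rnorm(n))
    dat$beta <- 0.3 - 0.5 * dat$x + bm + rnorm(n, 0, 0.4)
  })
  m1 <- fit_phylo_regression(dat, beta ~ x, C, method = "mcmc",
                             n_iter = 6000, burn_in = 1000, seed = 7)
  m2 <- fit_phylo_regression(dat, beta ~ x, C, method = "mcmc",
                             n_iter = 6000, burn_in = 1000, seed = 7)
  expect_identical(m1$coefficients, m2$coefficients)

  g <- fit_phylo_regression(dat, beta ~ x, C)
  i_x <- which(m1$coefficients$term == "x")
  expect_lt(abs(m1$coefficients$estimate[i_x] -
                  g$coefficients$estimate[i_x]),
            2 * m1$coefficients$se[i_x])
})

test_that("trait model sets run, skip no-contrast listings, honor weights", {
  withr::with_seed(24, {
    cfg <- sim_config(n_squares = 50, n_species = 40, n_years = 3, seed = 30)
    pool <- generate_species_pool(cfg)
    eff <- tibble::tibble(
      species_id = pool$species$species_id,
      metric = "occurrence", designation = "ALL",
      beta = pool$species$beta_occurrence + rnorm(40, 0, 0.2),
      se = runif(40, 0.1, 0.4), p_value = runif(40), n_units = 100L,
      excluded = FALSE, reason = NA_character_, dispersion = 1
    )
  })
  res <- run_trait_models(eff, pool$species, pool$phylogeny)
  expect_setequal(unique(res$model_id),
                  c("bocc", "schedule1", "annex1", "ecological"))
  eco <- dplyr::filter(res, model_id == "ecological")
  expect_true(all(c("log_mass", "log_pop", "log_change", "ssi", "sti") %in%
                    eco$term))
  expect_true(all(eco$conf_low <= eco$estimate &
                    eco$estimate <= eco$conf_high))

  # all species unlisted: schedule1 model skipped with a warning
  sp2 <- dplyr::mutate(pool$species, schedule1 = FALSE)
  expect_warning(res2 <- run_trait_models(eff, sp2, pool$phylogeny),
                 "no contrast in schedule1")
  expect_false("schedule1" %in% res2$model_id)

  # too few species: skipped entirely
  expect_warning(res3 <- run_trait_models(eff[1:5, ], pool$species,
                                          pool$phylogeny),
                 "fewer than")
  expect_equal(nrow(res3), 0)
})

test_that("trait-slope recovery covers the generating coefficient", {
  covered <- 0L
  for (s in 1:20) {
    withr::with_seed(1000 + s, {
      n <- 60
      ids <- sprintf("t%02d", 1:n)
      tree <- ape::rcoal(n, tip.label = ids)
      C <- brownian_covariance(tree)
      bm <- as.numeric(t(chol(unclass(C) + diag(1e-10, n))) %*% rnorm(n)) * 0.4
      dat <- tibble::tibble(species_id = ids, x = rnorm(n),
                            vi = runif(n, 0.01, 0.2))
      dat$beta <- 0.2 - 0.3 * dat$x + bm +
        rnorm(n, 0, sqrt(dat$vi))
    })
    f <- fit_phylo_regression(dat, beta ~ x, C, vi = dat$vi)
    co <- f$coefficients[f$coefficients$term == "x", ]
    if (co$conf_low <= -0.3 && -0.3 <= co$conf_high) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})
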