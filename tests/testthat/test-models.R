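test_that("design matrix drops arable, adds year blocks only when asked", {
  sq <- flat_squares(60, pa = runif(60))
  units <- tibble::tibble(square_id = sq$square_id,
                          occurrence = rbinom(60, 1, 0.5))
  des <- build_design(units, sq, "ALL", terms = character(0))
  mm <- design_matrix(des)
  expect_false("lc_arable" %in% colnames(mm))
  expect_equal(sum(grepl("^lc_", colnames(mm))), 9)
  expect_false(any(grepl("year", colnames(mm))))

  units$year <- rep(1:5, 12)
  des_y <- build_design(units, sq, "ALL",
                        terms = c("year", "pa_trend", "year_random"))
  mm_y <- design_matrix(des_y)
  expect_true(all(c("yearc", "I(yearc^2)", "pa:yearc") %in% colnames(mm_y)))
  expect_true(is.factor(des_y$data$year_f))

  # constant covariate dropped with a warning
  sq2 <- sq
  sq2$lc_conifer <- 0.1
  expect_warning(des_c <- build_design(units, sq2, "ALL",
                                       terms = character(0)),
                 "lc_conifer")
  expect_false("lc_conifer" %in% colnames(design_matrix(des_c)))
})

test_that("binary fit matches the closed-form 2x2 log odds ratio", {
  # presence 8/10 inside PA, 2/10 outside; no covariates
  sq <- flat_squares(20, pa = rep(c(1, 0), each = 10))
  sq[setdiff(lc_cols(), "lc_arable")] <- 0.1  # constant: auto-dropped
  sq$human_density <- 50
  units <- tibble::tibble(
    square_id = sq$square_id,
    occurrence = c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  )
  des <- suppressWarnings(build_design(units, sq, "ALL",
                                       terms = character(0)))
  fit <- fit_binary_model(des, species_id = "spX")
  expect_equal(fit$effects$beta, log((8 / 2) / (2 / 8)), tolerance = 1e-6)
  expect_equal(fit$effects$n_units, 20L)
  expect_false(fit$effects$excluded)
})

test_that("unpenalized binary fit equals glm's maximum likelihood", {
  set.seed(41)
  sq <- flat_squares(200, pa = runif(200))
  units <- tibble::tibble(square_id = sq$square_id,
                          occurrence = rbinom(200, 1, plogis(-0.3 +
                                                               0.8 * sq$pa_all)))
  des <- build_design(units, sq, "ALL", terms = character(0))
  fit <- fit_binary_model(des)
  oracle <- glm(des$formula, binomial(), des$data)
  expect_equal(fit$effects$beta, unname(coef(oracle)["pa"]), tolerance = 1e-5)
  expect_equal(fit$effects$se,
               unname(sqrt(diag(vcov(oracle)))["pa"]), tolerance = 1e-4)
})

test_that("n < k and separation produce the documented exclusions", {
  sq <- flat_squares(30, pa = runif(30))
  units <- tibble::tibble(square_id = sq$square_id[1:8],
                          occurrence = rbinom(8, 1, 0.5))
  des <- build_design(units, sq, "ALL", terms = character(0))
  fit <- fit_binary_model(des)
  expect_true(fit$effects$excluded)
  expect_equal(fit$effects$reason, "n_lt_k")

  # perfectly separated outcome on a binary PA
  sq2 <- flat_squares(40, pa = rep(c(0, 1), each = 20))
  units2 <- tibble::tibble(square_id = sq2$square_id,
                           occurrence = rep(c(0, 1), each = 20))
  des2 <- suppressWarnings(build_design(units2, sq2, "ALL",
                                        terms = character(0)))
  fit2 <- fit_binary_model(des2)
  expect_true(fit2$effects$excluded)
  expect_equal(fit2$effects$reason, "fit_failure")
})

test_that("abundance fit matches an independent NB oracle; Poisson limit", {
  # unpenalized design: our fit equals MASS::glm.nb maximum likelihood
  withr::with_seed(300, {
    sq <- flat_squares(250, pa = runif(250), seed = 301)
    units <- tidyr::expand_grid(square_id = sq$square_id, year = 1:4)
    sq_idx <- match(units$square_id, sq$square_id)
    units$count <- rnbinom(nrow(units),
                           mu = exp(1 + 0.4 * sq$pa_all[sq_idx]),
                           size = 2)
  })
  des <- build_design(units, sq, "ALL", response = "count",
                      terms = c("year", "pa_trend"))
  fit <- fit_abundance_model(des)
  oracle <- MASS::glm.nb(des$formula, data = des$data)
  ab <- fit$effects[fit$effects$metric == "abundance", ]
  expect_equal(ab$beta, unname(coef(oracle)["pa"]), tolerance = 1e-3)
  expect_equal(fit$theta, oracle$theta, tolerance = 0.05)

  # Poisson data: estimated NB size is large
  big <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    sqp <- flat_squares(150, pa = runif(150), seed = 500 + s)
    unitsp <- tidyr::expand_grid(square_id = sqp$square_id, year = 1:4) |>
      dplyr::mutate(count = rpois(dplyr::n(), 5))
    desp <- build_design(unitsp, sqp, "ALL", response = "count",
                         terms = c("year", "pa_trend", "year_random"))
    fitp <- fit_abundance_model(desp)
    if (!is.null(fitp$theta) && fitp$theta >= 50) big <- big + 1L
  }
  expect_gte(big, 9L)
})

test_that("ringing filters and the two-stratum productivity oracle hold", {
  rec <- tibble::tibble(
    site_id = c("a", "b", "c", "d"),
    species_id = "sp1", year = 1,
    n_juv = c(5, 5, 2, 30), n_ad = c(10, 10, 3, 30),
    n_early_visits = c(3, 4, 5, 6), n_late_visits = c(5, 4, 6, 6)
  )
  kept <- filter_ces_records(rec)
  expect_setequal(kept$site_id, c("b", "d"))  # a: 3 early; c: 5 captures

  # two strata, 30/100 vs 60/100 juveniles: beta = logit diff
  sq <- flat_squares(2, pa = c(0, 1))
  sq[setdiff(lc_cols(), "lc_arable")] <- 0.1
  sq$human_density <- 50
  units <- tibble::tibble(site_id = sq$square_id, year = c(1, 1),
                          n_juv = c(30, 60), n_ad = c(70, 40))
  des <- suppressWarnings(
    build_design(units, sq, "ALL", response = "cbind(n_juv, n_ad)",
                 terms = character(0)))
  fit <- fit_productivity_model(des)
  prod_beta <- fit$effects$beta[fit$effects$metric == "productivity"]
  expect_equal(prod_beta, qlogis(0.6) - qlogis(0.3), tolerance = 1e-6)
})

test_that("null p-values are approximately uniform", {
  ps <- replicate(200, {
    n <- 120
    pa <- runif(n)
    y <- rbinom(n, 1, 0.5)
    m <- glm(y ~ pa, binomial())
    summary(m)$coefficients["pa", 4]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("diagnostics flag injected zero inflation but not clean fits", {
  set.seed(77)
  sq <- flat_squares(300, pa = runif(300))
  units <- tidyr::expand_grid(square_id = sq$square_id, year = 1:3) |>
    dplyr::mutate(count = rpois(dplyr::n(), 4))
  des <- build_design(units, sq, "ALL", response = "count",
                      terms = c("year", "pa_trend", "year_random"))
  fit <- fit_abundance_model(des)
  expect_false(check_zero_inflation(fit, seed = 1)$flagged)
  expect_lt(abs(fit$effects$dispersion[1] - 1), 0.25)

  hits <- 0L
  for (s in 1:20) {
    set.seed(800 + s)
    units_zi <- units |>
      dplyr::mutate(count = ifelse(runif(dplyr::n()) < 0.5, 0L, count))
    des_zi <- build_design(units_zi, sq, "ALL", response = "count",
                           terms = c("year", "pa_trend", "year_random"))
    fit_zi <- fit_abundance_model(des_zi)
    if (check_zero_inflation(fit_zi, seed = s)$flagged) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("cross-species outlier rule excludes a planted extreme estimate", {
  set.seed(5)
  eff <- tibble::tibble(
    species_id = sprintf("sp%02d", 1:20), metric = "occurrence",
    designation = "ALL", beta = rnorm(20), se = 0.1,
    p_value = runif(20), n_units = 100L, excluded = FALSE,
    reason = NA_character_, dispersion = 1
  )
  eff$beta[1] <- median(eff$beta) + 10 * IQR(eff$beta)
  out <- diagnose_and_exclude(eff)
  expect_true(out$excluded[1])
  expect_equal(out$reason[1], "outlier")
  expect_false(any(out$excluded[-1]))

  # overdispersed binary fit excluded
  eff2 <- eff
  eff2$beta[1] <- 0
  eff2$dispersion[2] <- 3
  out2 <- diagnose_and_exclude(eff2)
  expect_true(out2$excluded[2])
  expect_equal(out2$reason[2], "overdispersed")
})
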