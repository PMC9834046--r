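#' Brownian-motion correlation matrix of a phylogeny
#'
#' Expected tip correlation under Brownian evolution: shared root-to-MRCA
#' path length scaled by tree depth, so the diagonal is 1 and a star tree
#' gives the identity. A tree that is not ultrametric within `tol` is
#' normalized per-tip (cov2cor of the path-length matrix) with a warning.
#'
#' @param phylogeny An `ape::phylo` tree.
#' @param tol Ultrametricity tolerance.
#' @return A species-by-species correlation matrix (class
#'   `"pa_phylo_cov"`), rows/columns named by tip label.
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' brownian_covariance(tree)["A", "B"]  # shared half the depth
brownian_covariance <- function(phylogeny, tol = 1e-6) {
  assert_that(inherits(phylogeny, "phylo"), "phylogeny must be an ape::phylo")
  V <- ape::vcv(phylogeny)
  depths <- diag(V)
  if (max(depths) - min(depths) > tol * max(depths)) {
    warning("tree not ultrametric; normalizing by per-tip depth")
    C <- stats::cov2cor(V)
  } else {
    C <- V / max(depths)
  }
  structure(C, class = c("pa_phylo_cov", class(C)))
}

# negative REML log-likelihood for Var = s2p*C + s2e*I + diag(vi)
neg_reml <- function(logpar, y, X, C, vi) {
  s2p <- exp(logpar[1])
  s2e <- exp(logpar[2])
  V <- s2p * C + diag(s2e + vi, nrow(C))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(1e10)
  beta <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  0.5 * (logdetV + 2 * sum(log(diag(ch2))) + sum(r * Vi_r))
}

#' Phylogenetically weighted regression of species effects on traits
#'
#' Generalized least squares with error covariance
#' `sigma2_p * C + sigma2_e * I + diag(vi)`, where `C` is the Brownian
#' correlation from [brownian_covariance()] and `vi` are known
#' per-species sampling variances (the squared SEs of the effect
#' estimates; inverse-variance weighting). The two free variance
#' components are estimated by restricted maximum likelihood on the log
#' scale. With a star tree, equal weights and any variance components, the
#' coefficients reduce to ordinary least squares.
#'
#' `method = "mcmc"` runs a single-chain Gibbs sampler for the equivalent
#' hierarchical model (phylogenetic random effect plus residual, with the
#' fixed `vi` as a measurement-error layer), with inverse-gamma priors
#' matching univariate inverse-Wishart (V = 1, nu = 0.002 for the residual;
#' V = 1, nu = 1 for the phylogenetic variance), flat priors on
#' coefficients, 50,000 iterations, 5,000 burn-in, thinning 25.
#'
#' @param data Tibble with the response and predictors.
#' @param formula Model formula, e.g. `beta ~ log_pop + ssi`.
#' @param C Phylogenetic correlation matrix whose dimnames cover
#'   `data$species_id` (rows are matched by species).
#' @param vi Optional numeric vector of known sampling variances (se^2),
#'   in `data` row order; `NULL` for unweighted.
#' @param method `"gls"` (default, deterministic) or `"mcmc"`.
#' @param n_iter,burn_in,thin MCMC chain settings.
#' @param seed Seed for the MCMC chain.
#' @return A `"pa_phylo_fit"`: coefficients with SEs and 95% intervals,
#'   variance components, the method used and (for MCMC) effective sample
#'   sizes.
#' @export
fit_phylo_regression <- function(data, formula, C, vi = NULL,
                                 method = c("gls", "mcmc"),
                                 n_iter = 50000, burn_in = 5000, thin = 25,
                                 seed = 1) {
  method <- match.arg(method)
  assert_that("species_id" %in% names(data), "data needs a species_id column")
  assert_that(all(data$species_id %in% rownames(C)),
              "species missing from the phylogenetic covariance")
  C <- unclass(C)[data$species_id, data$species_id]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  n <- length(y)
  if (is.null(vi)) vi <- rep(0, n)
  assert_that(length(vi) == n && all(vi >= 0), "vi must be n nonnegative values")
  if (qr(X)$rank < ncol(X)) {
    stop("singular trait design; collinear columns among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    message("phylogenetic covariance not PSD; adding 1e-8 ridge")
    C <- C + diag(1e-8, n)
  }

  if (method == "gls") {
    s2y <- var(as.numeric(y))
    opt <- optim(log(c(s2y / 2 + 1e-8, s2y / 2 + 1e-8)), neg_reml,
                 y = as.numeric(y), X = X, C = C, vi = vi,
                 method = "L-BFGS-B", lower = log(1e-10), upper = log(1e6))
    s2p <- exp(opt$par[1])
    s2e <- exp(opt$par[2])
    V <- s2p * C + diag(s2e + vi, n)
    Vi <- chol2inv(chol(V))
    XtViX_inv <- chol2inv(chol(crossprod(X, Vi %*% X)))
    beta <- XtViX_inv %*% crossprod(X, Vi %*% as.numeric(y))
    se <- sqrt(diag(XtViX_inv))
    coefs <- tibble::tibble(
      term = colnames(X), estimate = as.numeric(beta), se = se,
      conf_low = as.numeric(beta) - 1.96 * se,
      conf_high = as.numeric(beta) + 1.96 * se
    )
    out <- list(coefficients = coefs, sigma2_phylo = s2p, sigma2_resid = s2e,
                method = "gls", n = n, formula = formula,
                convergence = opt$convergence == 0, reml = -opt$value)
  } else {
    out <- gibbs_phylo(as.numeric(y), X, C, vi, n_iter, burn_in, thin, seed)
    out$formula <- formula
  }
  structure(out, class = "pa_phylo_fit")
}

# Gibbs sampler: y = X beta + a + m + e, a ~ N(0, s2a C), m_i ~ N(0, vi),
# e ~ N(0, s2e I); IG priors s2a ~ IG(nu_a/2, nu_a*V_a/2) with V=1, nu=1,
# s2e ~ IG(nu_e/2, nu_e*V_e/2) with V=1, nu=0.002; flat prior on beta.
gibbs_phylo <- function(y, X, C, vi, n_iter, burn_in, thin, seed) {
  n <- length(y)
  p <- ncol(X)
  eC <- eigen(C, symmetric = TRUE)
  lam <- pmax(eC$values, 1e-10)
  U <- eC$vectors
  XtX_inv <- chol2inv(chol(crossprod(X)))
  XtX_invXt <- XtX_inv %*% t(X)
  use_m <- any(vi > 0)
  nu_a <- 1; V_a <- 1; nu_e <- 0.002; V_e <- 1

  withr::with_seed(seed, {
    beta <- drop(XtX_invXt %*% y)
    a <- rep(0, n); m <- rep(0, n)
    s2a <- var(y) / 2 + 1e-6; s2e <- var(y) / 2 + 1e-6
    keep <- seq(burn_in + thin, n_iter, by = thin)
    draws_beta <- matrix(NA_real_, length(keep), p)
    draws_var <- matrix(NA_real_, length(keep), 2)
    k <- 0L
    for (it in seq_len(n_iter)) {
      # beta | rest
      resid <- y - a - m
      bm <- drop(XtX_invXt %*% resid)
      beta <- bm + drop(chol(s2e * XtX_inv) %*% rnorm(p))
      # a | rest (diagonal in the eigenbasis of C)
      r <- y - drop(X %*% beta) - m
      rs <- drop(crossprod(U, r))
      prec <- 1 / (lam * s2a) + 1 / s2e
      mu_s <- (rs / s2e) / prec
      a <- drop(U %*% (mu_s + rnorm(n) / sqrt(prec)))
      # m | rest (measurement-error layer)
      if (use_m) {
        r2 <- y - drop(X %*% beta) - a
        v_m <- 1 / (1 / pmax(vi, 1e-12) + 1 / s2e)
        m <- rnorm(n, v_m * r2 / s2e, sqrt(v_m))
        m[vi == 0] <- 0
      }
      # variance components
      aCa <- sum(drop(crossprod(U, a))^2 / lam)
      s2a <- 1 / rgamma(1, (n + nu_a) / 2, rate = (aCa + nu_a * V_a) / 2)
      e <- y - drop(X %*% beta) - a - m
      s2e <- 1 / rgamma(1, (n + nu_e) / 2,
                        rate = (sum(e^2) + nu_e * V_e) / 2)
      if (it %in% keep) {
        k <- k + 1L
        draws_beta[k, ] <- beta
        draws_var[k, ] <- c(s2a, s2e)
      }
    }
  })

  ess <- apply(draws_beta, 2, ess_acf)
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = colMeans(draws_beta),
    se = apply(draws_beta, 2, sd),
    conf_low = apply(draws_beta, 2, quantile, 0.025),
    conf_high = apply(draws_beta, 2, quantile, 0.975),
    ess = ess,
    ess_flag = ess < 200
  )
  list(coefficients = coefs,
       sigma2_phylo = mean(draws_var[, 1]),
       sigma2_resid = mean(draws_var[, 2]),
       method = "mcmc", n = n, n_samples = nrow(draws_beta),
       draws = draws_beta, convergence = all(ess >= 200))
}

# effective sample size from the initial-positive-sequence autocorrelation sum
ess_acf <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos) > 0) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' @export
print.pa_phylo_fit <- function(x, ...) {
  cat("<pa_phylo_fit> ", x$method, ", n = ", x$n,
      ", sigma2_phylo = ", signif(x$sigma2_phylo, 3),
      ", sigma2_resid = ", signif(x$sigma2_resid, 3), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Run the four trait model sets per metric and designation
#'
#' For each metric-designation combination with at least `min_species`
#' non-excluded species, fits: three conservation-listing models (`bocc`,
#' `schedule1`, `annex1`), each with the listing predictor plus log
#' population size; and the `ecological` model with log mass, log
#' population size, log population change, SSI, STI and habitat class.
#' The ecological model weights species by the inverse variance of their
#' effect estimates; the listing models are unweighted by default.
#' Productivity metrics are skipped by default (too few species in the
#' source scheme); listing models without contrast (a single listing level)
#' are skipped with a warning.
#'
#' @param effects A `"pa_effects"` tibble.
#' @param species Species trait tibble from [generate_species_pool()].
#' @param phylogeny The species phylogeny (`ape::phylo`).
#' @param metrics Metrics to analyse.
#' @param min_species Minimum non-excluded species per model.
#' @param weight_listing Also apply inverse-variance weights in the listing
#'   models.
#' @param method Passed to [fit_phylo_regression()].
#' @param seed Seed for MCMC chains.
#' @return A tibble of class `"pa_trait_results"`: one row per model term,
#'   with `metric`, `designation`, `model_id`, `term`, `estimate`, `se`,
#'   `conf_low`, `conf_high`, `n_species`, `method`.
#' @export
run_trait_models <- function(effects, species, phylogeny,
                             metrics = setdiff(pa_metrics(),
                                               c("productivity",
                                                 "productivity_trend")),
                             min_species = 10,
                             weight_listing = FALSE,
                             method = "gls", seed = 1) {
  C <- brownian_covariance(phylogeny)
  traits <- species |>
    dplyr::mutate(
      log_mass = log(.data$mass),
      log_pop = log(.data$pop_size_early),
      log_change = log(.data$pop_change),
      bocc = factor(.data$bocc, levels = c("green", "amber", "red"))
    )
  model_sets <- list(
    bocc = beta ~ bocc + log_pop,
    schedule1 = beta ~ schedule1 + log_pop,
    annex1 = beta ~ annex1 + log_pop,
    ecological = beta ~ log_mass + log_pop + log_change + ssi + sti + habitat
  )
  combos <- dplyr::distinct(effects, .data$metric, .data$designation) |>
    dplyr::filter(.data$metric %in% metrics)
  out <- purrr::pmap_dfr(combos, function(metric, designation) {
    eff <- effects |>
      dplyr::filter(.data$metric == .env$metric,
                    .data$designation == .env$designation,
                    !.data$excluded, !is.na(.data$beta)) |>
      dplyr::inner_join(traits, by = "species_id")
    if (nrow(eff) < min_species) {
      warning("skipping ", metric, "/", designation, ": fewer than ",
              min_species, " species")
      return(NULL)
    }
    purrr::imap_dfr(model_sets, function(fml, model_id) {
      if (model_id != "ecological") {
        pred <- all.vars(fml)[2]
        if (dplyr::n_distinct(eff[[pred]]) < 2) {
          warning("skipping ", model_id, " model for ", metric, "/",
                  designation, ": no contrast in ", pred)
          return(NULL)
        }
      }
      vi <- if (model_id == "ecological" || weight_listing) eff$se^2 else NULL
      fit <- tryCatch(
        fit_phylo_regression(eff, fml, C, vi = vi, method = method,
                             seed = seed),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NULL)
      fit$coefficients |>
        dplyr::select("term", "estimate", "se", "conf_low", "conf_high") |>
        dplyr::mutate(metric = metric, designation = designation,
                      model_id = model_id, n_species = nrow(eff),
                      method = fit$method, .before = 1)
    })
  })
  structure(out, class = c("pa_trait_results", class(out)))
}
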