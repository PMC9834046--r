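#' Build the covariate design for a species or community model
#'
#' Assembles the shared covariate structure of all PA models: nine linear
#' land-cover proportions (arable is omitted so the proportions do not sum to
#' 1 within the design), standardized log human density and its square, the
#' focal linear PA-fraction term for one designation, optional linear and
#' quadratic continuous-year terms with the PA-by-year interaction, an
#' optional year-factor random-effect block (ridge-penalized dummies, the
#' random-intercept analogue), a low-rank tensor-product smooth of easting,
#' northing and elevation, and an optional effort offset
#' `log(n_transect_squares)`.
#'
#' @param units Analysis-unit tibble carrying `square_id` (or `site_id`), the
#'   response column(s) and, when year terms are requested, `year`.
#' @param squares Landscape covariate tibble from [generate_landscape()] (or
#'   equivalent real covariates).
#' @param designation One of [pa_designations()]; its coverage fraction
#'   becomes the `pa` column.
#' @param response Name of the response column, or a two-sided expression
#'   such as `"cbind(n_juv, n_ad)"` for events-trials models.
#' @param terms Character vector of optional blocks: any of `"year"`
#'   (quadratic continuous year), `"pa_trend"` (PA-by-linear-year
#'   interaction), `"year_random"` (year-factor random effect), `"smooth"`
#'   (spatial-elevation tensor smooth), `"spatial_linear"` (standardized
#'   linear/quadratic elevation plus linear easting/northing, a
#'   low-dimensional spatial adjustment suited to matched re-analyses).
#'   Land cover, human density and the PA term are always present.
#' @param smooth_k Marginal basis dimension of the tensor smooth.
#' @param offset Name of a count-of-squares effort column in `squares` to
#'   include as a log offset, or `NULL`.
#' @return An object of class `"pa_design"`: list with `data`, `formula`,
#'   `designation`, `response`, `terms`, `n_coef` (total model coefficients,
#'   smooth basis included), `dropped` (constant covariates removed) and
#'   `parametric` (parametric column names).
#' @export
build_design <- function(units, squares, designation = "ALL",
                         response = "occurrence",
                         terms = "smooth",
                         smooth_k = 4, offset = NULL) {
  designation <- match.arg(toupper(designation), pa_designations())
  bad <- setdiff(terms, c("year", "pa_trend", "year_random", "smooth",
                          "spatial_linear"))
  assert_that(length(bad) == 0,
              paste("unknown design term(s):", paste(bad, collapse = ", ")))
  key <- if ("square_id" %in% names(units)) "square_id" else "site_id"
  sq <- squares
  if (key == "site_id") sq <- dplyr::rename(sq, site_id = "square_id")
  data <- dplyr::inner_join(units, sq, by = key)
  assert_that(nrow(data) > 0, "no analysis units matched the covariate table")

  data$pa <- data[[pa_column(designation)]]
  data$hd_std <- as.numeric(scale(log(data$human_density)))
  if (all(is.na(data$hd_std))) data$hd_std <- 0  # single unit: degenerate

  lc_keep <- setdiff(lc_cols(), "lc_arable")
  parametric <- c(lc_keep, "hd_std", "I(hd_std^2)", "pa")

  rhs <- c(lc_keep, "hd_std", "I(hd_std^2)", "pa")
  n_coef <- 1 + length(lc_keep) + 2 + 1

  if ("year" %in% terms || "pa_trend" %in% terms || "year_random" %in% terms) {
    assert_that("year" %in% names(data), "year terms requested without a year column")
    data$yearc <- data$year - mean(unique(data$year))
  }
  if ("year" %in% terms) {
    rhs <- c(rhs, "yearc", "I(yearc^2)")
    parametric <- c(parametric, "yearc", "I(yearc^2)")
    n_coef <- n_coef + 2
  }
  if ("pa_trend" %in% terms) {
    rhs <- c(rhs, "pa:yearc")
    parametric <- c(parametric, "pa:yearc")
    n_coef <- n_coef + 1
  }
  if ("year_random" %in% terms) {
    data$year_f <- factor(data$year)
    rhs <- c(rhs, "s(year_f, bs = \"re\")")
    n_coef <- n_coef + nlevels(data$year_f)
  }
  if ("smooth" %in% terms) {
    rhs <- c(rhs, sprintf("te(easting, northing, elevation, k = %d)", smooth_k))
    n_coef <- n_coef + smooth_k^3 - 1
  }
  if ("spatial_linear" %in% terms) {
    # low-dimensional spatial/elevation adjustment for matched re-analyses,
    # where a spatially clustered binary treatment is near-collinear with a
    # free-form spatial smooth
    data$elev_std <- as.numeric(scale(data$elevation))
    data$east_std <- as.numeric(scale(data$easting))
    data$north_std <- as.numeric(scale(data$northing))
    sp_terms <- c("elev_std", "I(elev_std^2)", "east_std", "north_std")
    rhs <- c(rhs, sp_terms)
    parametric <- c(parametric, sp_terms)
    n_coef <- n_coef + 4
  }

  # constant covariates carry no information and break the fit; drop them
  dropped <- character()
  for (cn in c(lc_keep, "hd_std")) {
    v <- data[[cn]]
    if (isTRUE(sd(v) == 0) || all(is.na(v))) {
      dropped <- c(dropped, cn)
      rhs <- setdiff(rhs, c(cn, if (cn == "hd_std") "I(hd_std^2)"))
      parametric <- setdiff(parametric, c(cn, if (cn == "hd_std") "I(hd_std^2)"))
      n_coef <- n_coef - ifelse(cn == "hd_std", 2, 1)
    }
  }
  if (length(dropped) > 0) {
    warning("constant covariate(s) dropped from design: ",
            paste(dropped, collapse = ", "))
  }

  if (!is.null(offset)) {
    assert_that(offset %in% names(data), "offset column not found")
    data$offset_log <- log(data[[offset]])
    rhs <- c(rhs, "offset(offset_log)")
  }

  structure(list(
    data = data,
    formula = as.formula(paste(response, "~", paste(rhs, collapse = " + "))),
    designation = designation,
    response = response,
    terms = terms,
    n_coef = n_coef,
    dropped = dropped,
    parametric = parametric
  ), class = "pa_design")
}

#' @export
print.pa_design <- function(x, ...) {
  cat("<pa_design> ", nrow(x$data), " units, designation ", x$designation,
      ", ", x$n_coef, " coefficients\n", sep = "")
  cat("  ", deparse1(x$formula), "\n", sep = "")
  invisible(x)
}

#' Parametric model matrix of a design
#'
#' Expands the parametric (non-smooth, non-random) block of a
#' [build_design()] object into a numeric matrix; useful for inspection and
#' for closed-form oracles in tests.
#'
#' @param design A `"pa_design"` object.
#' @return A numeric matrix with one column per parametric coefficient
#'   (intercept excluded).
#' @export
design_matrix <- function(design) {
  ff <- as.formula(paste("~", paste(design$parametric, collapse = " + ")))
  mm <- model.matrix(ff, data = design$data)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}
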