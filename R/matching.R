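# default covariate set used for matching and balance
match_covariates <- function() {
  c(setdiff(lc_cols(), "lc_arable"), "elevation", "human_density",
    "easting", "northing")
}

#' Assign matching treatment status
#'
#' Squares with designation coverage above `threshold` are treated; squares
#' with exactly zero coverage are controls; squares with small nonzero
#' coverage are excluded from matching.
#'
#' @param squares Landscape tibble.
#' @param designation One of [pa_designations()].
#' @param threshold Coverage fraction above which a square is treated
#'   (strictly greater; default 0.10).
#' @return The squares tibble with an added `role` column
#'   (`"treated"`/`"control"`/`"excluded"`).
#' @export
assign_treatment <- function(squares, designation = "ALL", threshold = 0.10) {
  pa <- squares[[pa_column(designation)]]
  role <- dplyr::case_when(pa > threshold ~ "treated",
                           pa == 0 ~ "control",
                           TRUE ~ "excluded")
  assert_that(any(role == "control"),
              "no zero-coverage squares: empty control pool")
  dplyr::mutate(squares, role = role)
}

#' Greedy Mahalanobis 1:1 matching without replacement
#'
#' Builds a matched counterfactual sample: each treated square (coverage >
#' threshold) is paired to its nearest zero-coverage control by Mahalanobis
#' distance in the matching covariates, without replacement and without
#' calipers. Treated units are processed in descending order of their
#' distance to the nearest available control, so hard-to-match units choose
#' first; when controls run out the remaining treated units are left
#' unmatched (partial matching). The distance metric uses the pooled
#' (treated + control) sample covariance; a tiny proportional ridge is added
#' only if it is singular.
#'
#' @param squares Landscape tibble.
#' @param designation One of [pa_designations()].
#' @param covariates Covariate columns defining the distance (default: the
#'   non-arable land-cover proportions, elevation, human density, easting
#'   and northing).
#' @param threshold Treatment threshold (strict; default 0.10).
#' @return An object of class `"pa_matched"`: list with `pairs` (tibble of
#'   `treated_id`, `control_id`, `distance`), `unmatched_treated`,
#'   `balance` (from [balance_table()]), `designation`, `threshold`,
#'   `covariates` and `roles`.
#' @export
mahalanobis_match <- function(squares, designation = "ALL",
                              covariates = match_covariates(),
                              threshold = 0.10) {
  assert_that(all(covariates %in% names(squares)),
              "matching covariates missing from squares")
  roles <- assign_treatment(squares, designation, threshold)
  tr <- dplyr::filter(roles, .data$role == "treated")
  ct <- dplyr::filter(roles, .data$role == "control")
  assert_that(nrow(tr) > 0, "no treated squares above the threshold")

  Xt <- as.matrix(tr[covariates])
  Xc <- as.matrix(ct[covariates])
  S <- cov(rbind(Xt, Xc))
  Sinv <- tryCatch(solve(S), error = function(e) {
    message("pooled covariance singular; ridge-stabilized")
    solve(S + diag(1e-8 * mean(diag(S)), ncol(S)))
  })

  # full treated x control squared-distance matrix
  L <- tryCatch(chol(Sinv), error = function(e) NULL)
  if (is.null(L)) {
    Sinv <- Sinv + diag(1e-10 * mean(diag(Sinv)), ncol(Sinv))
    L <- chol(Sinv)
  }
  Zt <- Xt %*% t(L)
  Zc <- Xc %*% t(L)
  d2 <- outer(rowSums(Zt^2), rowSums(Zc^2), "+") - 2 * tcrossprod(Zt, Zc)
  d2[d2 < 0] <- 0

  # Hardest-first (descending nearest-distance) pairing is best when every
  # treated unit can be matched; when controls are scarcer than treated,
  # partial matching should retain the treated units comparable to the
  # control pool, so the easiest are processed first instead.
  ord <- order(apply(d2, 1, min), decreasing = nrow(Xc) >= nrow(Xt))
  avail <- rep(TRUE, nrow(Xc))
  pairs <- vector("list", min(nrow(Xt), nrow(Xc)))
  k <- 0L
  unmatched <- character()
  for (i in ord) {
    if (!any(avail)) {
      unmatched <- c(unmatched, tr$square_id[i])
      next
    }
    di <- d2[i, ]
    di[!avail] <- Inf
    j <- which.min(di)  # ties break to the lowest control index
    avail[j] <- FALSE
    k <- k + 1L
    pairs[[k]] <- tibble::tibble(treated_id = tr$square_id[i],
                                 control_id = ct$square_id[j],
                                 distance = sqrt(d2[i, j]))
  }
  pairs <- dplyr::bind_rows(pairs[seq_len(k)])

  out <- structure(list(pairs = pairs,
                        unmatched_treated = sort(unmatched),
                        designation = designation,
                        threshold = threshold,
                        covariates = covariates,
                        roles = roles), class = "pa_matched")
  out$balance <- balance_table(out)
  out
}

#' @export
print.pa_matched <- function(x, ...) {
  cat("<pa_matched> ", x$designation, ": ", nrow(x$pairs), " pairs, ",
      length(x$unmatched_treated), " unmatched treated\n", sep = "")
  worst <- max(abs(x$balance$smd_after), na.rm = TRUE)
  cat("  worst post-matching |SMD| = ", round(worst, 3), "\n", sep = "")
  invisible(x)
}

#' Covariate balance of a matched set
#'
#' Standardized mean differences (treated minus control over the pooled
#' treated/control SD of the full samples) for every matching covariate,
#' before and after matching. Covariates with |SMD| >= 0.25 after matching
#' are flagged; a zero pooled SD yields SMD 0 with a flag.
#'
#' @param matched A `"pa_matched"` object.
#' @return A tibble: `covariate`, `smd_before`, `smd_after`, `flag_imbalanced`,
#'   `flag_zero_sd`.
#' @export
balance_table <- function(matched) {
  roles <- matched$roles
  tr <- dplyr::filter(roles, .data$role == "treated")
  ct <- dplyr::filter(roles, .data$role == "control")
  tr_m <- dplyr::filter(tr, .data$square_id %in% matched$pairs$treated_id)
  ct_m <- dplyr::filter(ct, .data$square_id %in% matched$pairs$control_id)
  purrr::map_dfr(matched$covariates, function(cv) {
    sd_pool <- sqrt((var(tr[[cv]]) + var(ct[[cv]])) / 2)
    smd <- function(a, b) {
      if (is.na(sd_pool) || sd_pool == 0) 0 else (mean(a) - mean(b)) / sd_pool
    }
    tibble::tibble(
      covariate = cv,
      smd_before = smd(tr[[cv]], ct[[cv]]),
      smd_after = smd(tr_m[[cv]], ct_m[[cv]]),
      flag_zero_sd = is.na(sd_pool) || sd_pool == 0
    )
  }) |>
    dplyr::mutate(flag_imbalanced = abs(.data$smd_after) >= 0.25)
}

#' Matched-sample covariate-adjusted re-analysis
#'
#' Re-fits a species model on the matched squares only, replacing the
#' continuous coverage fraction with a binary treated/control indicator
#' while keeping the covariate adjustments (imbalances can remain after
#' matching). Returns the effects tibble of the refit.
#'
#' @param matched A `"pa_matched"` object.
#' @param units Analysis-unit tibble as in [build_design()].
#' @param response Response column in `units`.
#' @param metric Metric label for the returned effect row.
#' @param species_id Species label for the returned effect row.
#' @param terms,smooth_k,offset Passed to [build_design()].
#' @return A `"pa_fit"` object (binary PA indicator coefficient).
#' @export
fit_matched_model <- function(matched, units, response, metric = "occurrence",
                              species_id = "sp", terms = "smooth",
                              smooth_k = 4, offset = NULL) {
  keep_ids <- c(matched$pairs$treated_id, matched$pairs$control_id)
  sq <- matched$roles |>
    dplyr::filter(.data$square_id %in% keep_ids) |>
    dplyr::mutate(pa_binary = as.numeric(.data$role == "treated"))
  # the binary indicator stands in for the coverage fraction
  sq[[pa_column(matched$designation)]] <- sq$pa_binary
  key <- if ("square_id" %in% names(units)) "square_id" else "site_id"
  units <- units[units[[key]] %in% keep_ids, , drop = FALSE]
  des <- build_design(units, dplyr::select(sq, -"role", -"pa_binary"),
                      matched$designation, response = response,
                      terms = terms, smooth_k = smooth_k, offset = offset)
  if (grepl("cbind", response)) {
    fit_productivity_model(des, species_id = species_id)
  } else if (identical(response, "count")) {
    fit_abundance_model(des, species_id = species_id)
  } else {
    fit_binary_model(des, metric = metric, species_id = species_id)
  }
}
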