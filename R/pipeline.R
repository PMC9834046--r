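#' Pipeline run configuration
#'
#' Bundles a simulation configuration with the analysis settings of a full
#' pipeline run.
#'
#' @param sim A [sim_config()] object (its `seed` drives all stages).
#' @param out_dir Output directory for artifact files, or `NULL` to skip
#'   writing.
#' @param alpha Significance threshold used in the summaries.
#' @param designations Designations to analyse.
#' @param match_threshold Treatment threshold for matching.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "classify", "fit", "summarize", "match", "traits",
#'   "community")`. Later stages silently require their upstream inputs.
#' @param smooth_k Tensor-smooth basis dimension passed to the model fits.
#' @return A list of class `"pa_run_config"`.
#' @export
run_config <- function(sim = sim_config(),
                       out_dir = NULL,
                       alpha = 0.05,
                       designations = "ALL",
                       match_threshold = 0.10,
                       stages = c("simulate", "classify", "fit", "summarize",
                                  "match", "traits", "community"),
                       smooth_k = 4) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stages <- match.arg(stages, c("simulate", "classify", "fit", "summarize",
                                "match", "traits", "community"),
                      several.ok = TRUE)
  structure(list(sim = sim, out_dir = out_dir, alpha = alpha,
                 designations = designations,
                 match_threshold = match_threshold, stages = stages,
                 smooth_k = smooth_k),
            class = "pa_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate the three
#' monitoring streams; classify atlas transitions; fit per-species PA
#' models; summarize effects across species; build the matched
#' counterfactual with balance diagnostics; run the trait models; compute
#' community metrics and their PA models. All randomness derives from
#' `config$sim$seed`, so a rerun with the same configuration is
#' reproducible, and disabling a downstream stage never changes upstream
#' outputs. When `config$out_dir` is set, every table is written as CSV
#' (plus the newick tree and a markdown report).
#'
#' @param config A [run_config()] object.
#' @return A list of class `"pa_run"` with elements `config`, `seed`,
#'   `config_hash`, `sim`, `outcomes`, `inclusion`, `effects`, `summary`,
#'   `matched` (list by designation), `matched_balance`, `trait_models`,
#'   `community`, `community_models` (stages not run are `NULL`).
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(sim_config(n_squares = 120, n_species = 6,
#'                                           n_years = 6, seed = 1),
#'                                smooth_k = 3))
#' run$summary
#' }
run_pipeline <- function(config) {
  assert_that(inherits(config, "pa_run_config"), "config must be a pa_run_config")
  on <- function(s) s %in% config$stages
  hashable <- unclass(config)
  hashable$out_dir <- NULL  # where outputs land must not change their content
  res <- list(config = config, seed = config$sim$seed,
              config_hash = rlang::hash(hashable))

  if (on("simulate")) {
    res$sim <- simulate_survey_data(config$sim)
  }

  if (on("classify")) {
    assert_that(!is.null(res$sim), "classify stage needs simulated data")
    atlas_f <- filter_breeding_evidence(res$sim$atlas)
    res$outcomes <- classify_transitions(atlas_f)
    res$inclusion <- species_inclusion_filter(res$outcomes, res$sim$species)
  }

  if (on("fit")) {
    assert_that(!is.null(res$sim), "fit stage needs simulated data")
    res$effects <- fit_species_effects(res$sim,
                                       designations = config$designations,
                                       smooth_k = config$smooth_k) |>
      diagnose_and_exclude()
  }

  if (on("summarize")) {
    assert_that(!is.null(res$effects), "summarize stage needs fitted effects")
    res$summary <- summarize_effects(res$effects, alpha = config$alpha)
  }

  if (on("match")) {
    assert_that(!is.null(res$sim), "match stage needs simulated data")
    res$matched <- lapply(setNames(config$designations, config$designations),
                          function(d) {
                            mahalanobis_match(res$sim$squares, d,
                                              threshold = config$match_threshold)
                          })
    res$matched_balance <- purrr::imap_dfr(res$matched, function(m, d) {
      dplyr::mutate(m$balance, designation = d, .before = 1)
    })
  }

  if (on("traits")) {
    assert_that(!is.null(res$effects), "traits stage needs fitted effects")
    res$trait_models <- suppressWarnings(
      run_trait_models(res$effects, res$sim$species, res$sim$phylogeny,
                       seed = stage_seed(config$sim$seed, 707L))
    )
  }

  if (on("community")) {
    assert_that(!is.null(res$sim), "community stage needs simulated data")
    res$community <- community_metrics(res$sim$counts, res$sim$species)
    res$community_models <- purrr::map_dfr(
      config$designations,
      function(d) fit_community_models(res$community, res$sim$squares, d,
                                       smooth_k = config$smooth_k))
  }

  res <- structure(res, class = "pa_run")
  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$sim)) write_simulation(run$sim, dir)
  wr <- function(x, f) if (!is.null(x)) readr::write_csv(x, file.path(dir, f))
  wr(run$outcomes, "occupancy_outcomes.csv")
  wr(run$inclusion, "species_inclusion.csv")
  wr(run$effects, "species_effects.csv")
  wr(run$summary, "summary.csv")
  if (!is.null(run$matched)) {
    pairs <- purrr::imap_dfr(run$matched, function(m, d) {
      dplyr::mutate(m$pairs, designation = d, .before = 1)
    })
    readr::write_csv(pairs, file.path(dir, "matched_pairs.csv"))
    wr(run$matched_balance, "balance.csv")
  }
  wr(run$trait_models, "trait_models.csv")
  wr(run$community, "community_metrics.csv")
  wr(run$community_models, "community_models.csv")
  writeLines(write_report(run), file.path(dir, "report.md"))
  invisible(dir)
}

#' Render a plain-text pipeline report
#'
#' Deterministic markdown report with one section per stage: simulation
#' summary, occupancy classification, per-species effects, cross-species
#' summaries (percent significantly positive/negative and mean +/- SE per
#' metric-designation), matching balance, trait models and community
#' models. Sections whose stage did not run are marked "not run".
#'
#' @param run A `"pa_run"` object.
#' @return A character vector of report lines.
#' @export
write_report <- function(run) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "fg")
  lines <- c("# Protected-area effectiveness report", "",
             paste0("seed: ", run$seed),
             paste0("config hash: ", run$config_hash), "")
  sec <- function(title, body) {
    c(paste0("## ", title), "",
      if (is.null(body)) "not run" else body, "")
  }

  lines <- c(lines, sec("Simulation", if (!is.null(run$sim)) {
    c(paste0("squares: ", nrow(run$sim$squares)),
      paste0("species: ", nrow(run$sim$species)),
      paste0("years: ", run$sim$config$n_years),
      paste0("atlas records: ", nrow(run$sim$atlas)),
      paste0("count records: ", nrow(run$sim$counts)),
      paste0("ringing records: ", nrow(run$sim$ringing)))
  }))

  lines <- c(lines, sec("Occupancy classification", if (!is.null(run$outcomes)) {
    c(paste0("square-species rows: ", nrow(run$outcomes)),
      paste0("species retained: ", sum(run$inclusion$retained), " of ",
             nrow(run$inclusion)))
  }))

  lines <- c(lines, sec("Species effects", if (!is.null(run$effects)) {
    c(paste0("fitted rows: ", nrow(run$effects)),
      paste0("excluded: ", sum(run$effects$excluded)))
  }))

  lines <- c(lines, sec("Cross-species summaries", if (!is.null(run$summary)) {
    unlist(lapply(seq_len(nrow(run$summary)), function(i) {
      s <- run$summary[i, ]
      n_sig <- s$n_pos_sig + s$n_neg_sig
      paste0(s$metric, " / ", s$designation, ": ",
             round(100 * s$n_pos_sig / max(1, s$n_total)), "% sig positive, ",
             round(100 * s$n_neg_sig / max(1, s$n_total)), "% sig negative ",
             "(of ", s$n_total, "); mean = ", fmt(s$mean_effect),
             " +/- ", fmt(s$se),
             if (!is.na(s$prop_test_p)) paste0("; sign-test p = ",
                                               fmt(s$prop_test_p)) else "")
    }))
  }))

  lines <- c(lines, sec("Matching", if (!is.null(run$matched)) {
    unlist(lapply(names(run$matched), function(d) {
      m <- run$matched[[d]]
      paste0(d, ": ", nrow(m$pairs), " pairs, ",
             length(m$unmatched_treated), " unmatched treated; worst |SMD| ",
             fmt(max(abs(m$balance$smd_after))))
    }))
  }))

  lines <- c(lines, sec("Trait models", if (!is.null(run$trait_models)) {
    if (nrow(run$trait_models) == 0) "no trait models could be fitted" else
      paste0(nrow(run$trait_models), " coefficient rows over ",
             dplyr::n_distinct(run$trait_models$model_id), " model sets")
  }))

  lines <- c(lines, sec("Community", if (!is.null(run$community_models)) {
    unlist(lapply(seq_len(nrow(run$community_models)), function(i) {
      cm <- run$community_models[i, ]
      paste0(cm$metric, " / ", cm$designation, " ", cm$term, ": ",
             fmt(cm$estimate), " +/- ", fmt(cm$se))
    }))
  }))

  lines
}

#' @export
print.pa_run <- function(x, ...) {
  cat(write_report(x), sep = "\n")
  invisible(x)
}
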