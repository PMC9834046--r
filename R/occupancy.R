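#' Apply the 10-km breeding-evidence filter to atlas records
#'
#' A presence record whose containing 10-km square has no probable or
#' confirmed breeding record of that species in the same period is treated
#' as an absence (the sighting is assumed to be a non-breeder). All other
#' records are unchanged. The filter is applied within each atlas period
#' separately.
#'
#' @param atlas Atlas records with `square_id`, `easting`, `northing`,
#'   `species_id`, `period`, `present`, `evidence`.
#' @return The atlas tibble with `present` demoted where the filter applies
#'   and an added logical `evidence_filtered` marking demoted records.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   square_id = c("a", "b"), easting = c(0, 2), northing = c(0, 0),
#'   species_id = "sp1", period = 1,
#'   present = c(TRUE, TRUE), evidence = c("possible", "confirmed")
#' )
#' filter_breeding_evidence(rec)$present  # both kept: shared 10-km square
filter_breeding_evidence <- function(atlas) {
  bad <- atlas$present & is.na(atlas$evidence)
  if (any(bad)) {
    warning(sum(bad), " presence record(s) lack an evidence code; dropped")
    atlas <- atlas[!bad, ]
  }
  atlas |>
    dplyr::mutate(.block = block10(.data$easting, .data$northing)) |>
    dplyr::group_by(.data$.block, .data$species_id, .data$period) |>
    dplyr::mutate(
      .has_breeder = any(.data$present &
                           .data$evidence %in% c("probable", "confirmed")),
      evidence_filtered = .data$present & !.data$.has_breeder,
      present = .data$present & .data$.has_breeder
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".block", -".has_breeder")
}

#' Classify two-period occupancy transitions
#'
#' Turns (filtered) per-period presence into per-tetrad outcomes:
#' * `occurrence` — 1 if the species was present in either surveyed period;
#' * `colonization` — defined only for tetrads surveyed in both periods that
#'   were unoccupied in period 1; 1 if occupied in period 2;
#' * `persistence` — defined only for tetrads surveyed in both periods that
#'   were occupied in period 1; 1 if still occupied in period 2 (persistence
#'   is the complement of extinction).
#'
#' Undefined transitions are `NA` with the reason recorded. A tetrad never
#' has both transitions defined, and for tetrads surveyed in both periods the
#' counts of defined colonizations and persistences sum to the number of
#' such tetrads.
#'
#' @param atlas Atlas records (ideally after [filter_breeding_evidence()]).
#' @return A tibble with one row per square-species: `square_id`,
#'   `species_id`, `surveyed_both`, `occurrence`, `colonization`,
#'   `persistence`, `transition_reason`.
#' @export
classify_transitions <- function(atlas) {
  wide <- atlas |>
    dplyr::distinct(.data$square_id, .data$species_id, .data$period,
                    .keep_all = TRUE) |>
    dplyr::select("square_id", "species_id", "period", "present") |>
    tidyr::pivot_wider(names_from = "period", values_from = "present",
                       names_prefix = "p")
  if (!"p1" %in% names(wide)) wide$p1 <- NA
  if (!"p2" %in% names(wide)) wide$p2 <- NA
  wide |>
    dplyr::mutate(
      surveyed_both = !is.na(.data$p1) & !is.na(.data$p2),
      occurrence = as.integer(
        dplyr::coalesce(.data$p1, FALSE) | dplyr::coalesce(.data$p2, FALSE)),
      colonization = dplyr::if_else(
        .data$surveyed_both & !.data$p1, as.integer(.data$p2), NA_integer_),
      persistence = dplyr::if_else(
        .data$surveyed_both & .data$p1, as.integer(.data$p2), NA_integer_),
      transition_reason = dplyr::case_when(
        !.data$surveyed_both ~ "not_surveyed_both",
        .data$p1 ~ "occupied_p1_persistence_only",
        TRUE ~ "unoccupied_p1_colonization_only"
      )
    ) |>
    dplyr::select("square_id", "species_id", "surveyed_both", "occurrence",
                  "colonization", "persistence", "transition_reason")
}

#' Species inclusion filter for the atlas analysis
#'
#' Retains species that are native and occupy at least `min_tetrads` tetrads
#' (presence in either period, after evidence filtering).
#'
#' @param outcomes Output of [classify_transitions()].
#' @param species Species tibble with `species_id` and logical `native`.
#' @param min_tetrads Minimum occupied-tetrad count (default 20; species in
#'   fewer are excluded).
#' @return A tibble with `species_id`, `n_tetrads`, `native`, `retained` and
#'   `exclusion_reason`.
#' @export
species_inclusion_filter <- function(outcomes, species, min_tetrads = 20) {
  outcomes |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(n_tetrads = sum(.data$occurrence, na.rm = TRUE)) |>
    dplyr::right_join(dplyr::select(species, "species_id", "native"),
                      by = "species_id") |>
    dplyr::mutate(
      n_tetrads = dplyr::coalesce(.data$n_tetrads, 0L),
      retained = .data$native & .data$n_tetrads >= min_tetrads,
      exclusion_reason = dplyr::case_when(
        !.data$native ~ "non_native",
        .data$n_tetrads < min_tetrads ~ "fewer_than_min_tetrads",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::arrange(.data$species_id)
}
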