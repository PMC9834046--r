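#' Designation and metric vocabularies
#'
#' `pa_designations()` returns the designation labels understood throughout the
#' package: `"ALL"` (any statutory protected area), `"SSSI"` (Sites of Special
#' Scientific Interest, national), `"SPA"` (Special Protection Areas, targeted
#' at birds) and `"SAC"` (Special Areas of Conservation, targeted at habitats).
#' `pa_metrics()` returns the seven population metrics for which PA
#' coefficients are estimated.
#'
#' @return A character vector.
#' @export
pa_designations <- function() c("ALL", "SSSI", "SPA", "SAC")

#' @rdname pa_designations
#' @export
pa_metrics <- function() {
  c("occurrence", "colonization", "persistence",
    "abundance", "abundance_trend",
    "productivity", "productivity_trend")
}

# landcover classes; proportions per square sum to 1
lc_classes <- function() {
  c("broadleaf", "conifer", "arable", "improved_grass", "seminat_grass",
    "mountain_heath_bog", "saltwater", "freshwater", "coastal", "urban")
}

lc_cols <- function() paste0("lc_", lc_classes())

#' Column name holding the PA fraction for a designation
#'
#' Landscape tables store one coverage-fraction column per designation
#' (`pa_all`, `pa_sssi`, `pa_spa`, `pa_sac`); this maps the designation label
#' to its column.
#'
#' @param designation One of `pa_designations()`.
#' @return A string.
#' @export
pa_column <- function(designation) {
  designation <- match.arg(toupper(designation), pa_designations())
  paste0("pa_", tolower(designation))
}

# 10-km parent block of a square; 0-based axis-aligned grid
block10 <- function(easting, northing) {
  paste0(floor(easting / 10), "_", floor(northing / 10))
}

# deterministic child seed for a pipeline stage (kept within 32-bit range)
stage_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
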