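#' Read a long-format trait observation table
#'
#' Reads a delimited (comma-separated, header row) trait table and validates
#' every row against the data model: one row is one measurement of one trait
#' on one individual, with taxonomic, dataset and spatial provenance.
#' Invalid rows are excluded and reported with row numbers and reasons,
#' never silently coerced. Coordinates must be either both present or both
#' absent; records without coordinates are legal (they are kept for cleaning
#' and variance analyses but excluded from spatial and climate operations).
#'
#' @param path Path to a CSV file with (at least) the mandatory columns
#'   `record_id`, `species`, `genus`, `functional_group`, `dataset_id`,
#'   `site_id`, `trait`, `value`; optional `latitude`, `longitude`, `units`.
#' @return A tibble of valid trait records. Attribute `"diagnostics"` holds
#'   a tibble (`row`, `record_id`, `reason`) describing every rejected row.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop_tp("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_trait_records(tibble::as_tibble(raw))
}

#' @rdname read_trait_table
#' @param records A trait-record tibble (e.g. from [generate_database()]).
#' @export
write_trait_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate trait records against the data model
#'
#' @param records A data frame of candidate trait records.
#' @return The valid rows as a tibble, with rejected rows described in the
#'   `"diagnostics"` attribute.
#' @export
validate_trait_records <- function(records) {
  mandatory <- c("record_id", "species", "genus", "functional_group",
                 "dataset_id", "site_id", "trait", "value")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols)) {
    stop_tp("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"latitude" %in% names(records)) records$latitude <- NA_real_
  if (!"longitude" %in% names(records)) records$longitude <- NA_real_
  if (!"units" %in% names(records)) records$units <- NA_character_
  records <- tibble::as_tibble(records)

  n <- nrow(records)
  reason <- character(n)
  bad <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reason[cond & reason == ""] <<- why
  }
  bad(is.na(records$value) | !is.finite(records$value), "missing value")
  bad(records$value <= 0, "non-positive value")
  bad(!records$trait %in% TRAIT_LEVELS, "unknown trait")
  bad(is.na(records$latitude) != is.na(records$longitude),
      "incomplete coordinates")
  bad(!is.na(records$latitude) &
        (records$latitude < -90 | records$latitude > 90),
      "latitude out of range")
  bad(!is.na(records$longitude) &
        (records$longitude < -180 | records$longitude > 180),
      "longitude out of range")

  keep <- reason == ""
  diagnostics <- tibble::tibble(row = which(!keep),
                                record_id = records$record_id[!keep],
                                reason = reason[!keep])
  out <- records[keep, ]
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Read a site table
#'
#' @param path CSV with columns `site_id`, `latitude`, `longitude`,
#'   `mean_annual_temperature`, `class_temperature`.
#' @return A tibble.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop_tp("file not found: ", path)
  sites <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  needed <- c("site_id", "latitude", "longitude", "mean_annual_temperature",
              "class_temperature")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    stop_tp("missing site columns: ", paste(missing_cols, collapse = ", "))
  }
  sites
}

#' Read a species list (one name per line)
#'
#' @param path Text file with one species name per line; blank lines ignored.
#' @return Character vector of species names.
#' @export
read_species_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(x)
  x[nzchar(x)]
}

check_site_coverage <- function(records, site_table) {
  unknown <- setdiff(unique(records$site_id), site_table$site_id)
  if (length(unknown)) {
    stop_tp("site table does not cover site_id(s): ",
            paste(sort(unknown), collapse = ", "))
  }
  invisible(TRUE)
}

#' Select the biome species pool
#'
#' The pool is the union of a plot-derived species list (species recorded in
#' vegetation survey plots) and all species with at least one trait record
#' at a collection site whose mean annual temperature is below the
#' threshold. This mirrors defining a cold-biome pool as plot species plus
#' species collected at sites with MAT below 0 degrees C.
#'
#' @param records Trait records.
#' @param plot_species_list Character vector of species from survey plots.
#' @param site_table Site table covering all referenced `site_id`s.
#' @param mat_threshold_C Threshold on site mean annual temperature
#'   (default 0).
#' @return Sorted character vector of pool species.
#' @export
select_biome_pool <- function(records, plot_species_list, site_table,
                              mat_threshold_C = 0) {
  check_site_coverage(records, site_table)
  cold_sites <- site_table$site_id[
    site_table$mean_annual_temperature < mat_threshold_C]
  cold_species <- unique(records$species[records$site_id %in% cold_sites])
  sort(unique(c(plot_species_list, cold_species)))
}

#' Select the extreme (high-arctic / cold-site) species subset
#'
#' Species with at least one record north of the Arctic Circle (latitude
#' greater than 66.5 degrees N) or at a site with mean annual temperature
#' below 0 degrees C. Used for sensitivity reruns restricted to the
#' climatically most extreme part of the data.
#'
#' @inheritParams select_biome_pool
#' @param arctic_circle_lat Latitude threshold in degrees N (default 66.5).
#' @return Sorted character vector of species names.
#' @export
select_extreme_subset <- function(records, site_table,
                                  mat_threshold_C = 0,
                                  arctic_circle_lat = 66.5) {
  check_site_coverage(records, site_table)
  x <- dplyr::left_join(
    records,
    dplyr::select(site_table, "site_id", site_lat = "latitude",
                  mat = "mean_annual_temperature"),
    by = "site_id")
  lat <- ifelse(is.na(x$latitude), x$site_lat, x$latitude)
  hit <- (!is.na(lat) & lat > arctic_circle_lat) |
    (!is.na(x$mat) & x$mat < mat_threshold_C)
  sort(unique(x$species[hit]))
}

#' Assign species to temperature classes
#'
#' Computes, for each species, the unweighted mean of `class_temperature`
#' over the unique sites at which the species has georeferenced records, and
#' classifies: mean below `cold_max` is "cold", above `warm_min` is "warm",
#' otherwise "mid". Boundary values exactly at the thresholds fall in "mid"
#' (the class definitions use strict inequalities). Species with no
#' georeferenced site are flagged as unclassified (class `NA`), never
#' dropped silently.
#'
#' @inheritParams select_biome_pool
#' @param cold_max Upper bound (exclusive) of the cold class, degrees C.
#' @param warm_min Lower bound (exclusive) of the warm class, degrees C.
#' @return Tibble with columns `species`, `mean_class_temperature`,
#'   `n_sites`, `temperature_class` (factor cold/mid/warm, `NA` when
#'   unclassifiable).
#' @export
assign_temperature_class <- function(records, site_table,
                                     cold_max = -1.0, warm_min = 1.0) {
  check_site_coverage(records, site_table)
  geo <- records[!is.na(records$latitude) & !is.na(records$longitude), ]
  per_site <- dplyr::distinct(geo, .data$species, .data$site_id)
  per_site <- dplyr::left_join(
    per_site,
    dplyr::select(site_table, "site_id", "class_temperature"),
    by = "site_id")
  cls <- per_site %>%
    dplyr::group_by(.data$species) %>%
    dplyr::summarise(mean_class_temperature = mean(.data$class_temperature),
                     n_sites = dplyr::n(), .groups = "drop")
  all_species <- tibble::tibble(species = sort(unique(records$species)))
  cls <- dplyr::left_join(all_species, cls, by = "species")
  cls$n_sites[is.na(cls$n_sites)] <- 0L
  cls$temperature_class <- factor(
    dplyr::case_when(
      is.na(cls$mean_class_temperature) ~ NA_character_,
      cls$mean_class_temperature < cold_max ~ "cold",
      cls$mean_class_temperature > warm_min ~ "warm",
      TRUE ~ "mid"),
    levels = c("cold", "mid", "warm"))
  cls
}
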