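#' Configuration for hierarchical trait cleaning
#'
#' Thresholds for the two-part cleaning procedure: (i) within-dataset
#' duplicate removal driven by the duplicated-value ratio, and (ii) a
#' hierarchical error-risk screen applied per trait in three ordered steps
#' (global, dataset-level, species-level). The error risk of an observation
#' is its absolute deviation from the mean of its reference group (excluding
#' the observation itself) in units of the group's standard deviation.
#'
#' @param duplicate_ratio_threshold Datasets whose duplicated-value ratio
#'   strictly exceeds this are deduplicated (default 0.30).
#' @param global_risk Error-risk threshold against the entire distribution
#'   of a trait (default 8.0).
#' @param dataset_species_risk Threshold for per-dataset species means of
#'   species present in at least `min_datasets_for_species_rule` datasets
#'   (default 3.0).
#' @param dataset_genus_risk Threshold for per-dataset genus means used for
#'   species present in fewer datasets (default 3.5).
#' @param min_datasets_for_species_rule Minimum number of distinct datasets
#'   for the species-mean dataset rule (default 4).
#' @param species_risk_min,species_risk_max Species-level threshold
#'   endpoints: `species_risk_min` for fewer than `species_risk_n_low`
#'   records, `species_risk_max` for more than `species_risk_n_high`
#'   records, linear interpolation in between (defaults 2.25 and 4.0).
#' @param species_risk_n_low,species_risk_n_high Record-count endpoints of
#'   the interpolation (defaults 10 and 30).
#' @param min_records_species_rule Species with this many records or fewer
#'   are left untouched by the species-level step (default 4).
#' @param sd_excludes_x Should the standard deviation, like the mean,
#'   exclude the assessed observation? Default `TRUE`, consistent with the
#'   excluded mean; set `FALSE` to use the full-group standard deviation.
#' @param dataset_means_log Compute dataset-level species/genus means on the
#'   log scale instead of the natural scale (default `FALSE`).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(duplicate_ratio_threshold = 0.30,
                            global_risk = 8.0,
                            dataset_species_risk = 3.0,
                            dataset_genus_risk = 3.5,
                            min_datasets_for_species_rule = 4,
                            species_risk_min = 2.25,
                            species_risk_max = 4.0,
                            species_risk_n_low = 10,
                            species_risk_n_high = 30,
                            min_records_species_rule = 4,
                            sd_excludes_x = TRUE,
                            dataset_means_log = FALSE) {
  if (species_risk_min > species_risk_max) {
    stop_tp("species_risk_min must be <= species_risk_max")
  }
  if (species_risk_n_low >= species_risk_n_high) {
    stop_tp("species_risk_n_low must be < species_risk_n_high")
  }
  thr <- c(duplicate_ratio_threshold, global_risk, dataset_species_risk,
           dataset_genus_risk, species_risk_min, species_risk_max)
  if (any(thr <= 0)) stop_tp("all thresholds must be > 0")
  structure(list(duplicate_ratio_threshold = duplicate_ratio_threshold,
                 global_risk = global_risk,
                 dataset_species_risk = dataset_species_risk,
                 dataset_genus_risk = dataset_genus_risk,
                 min_datasets_for_species_rule = min_datasets_for_species_rule,
                 species_risk_min = species_risk_min,
                 species_risk_max = species_risk_max,
                 species_risk_n_low = species_risk_n_low,
                 species_risk_n_high = species_risk_n_high,
                 min_records_species_rule = min_records_species_rule,
                 sd_excludes_x = sd_excludes_x,
                 dataset_means_log = dataset_means_log),
            class = "cleaning_config")
}

#' Error risk of an observation within its reference group
#'
#' `|x - mean(group without x)| / sd`, where the standard deviation is the
#' sample standard deviation (n-1 denominator) of the group without `x` when
#' `sd_excludes_x`, and of the full group otherwise. When the reference
#' spread is zero the risk is 0 if `x` equals the common value and `Inf`
#' otherwise (always removable).
#'
#' @param x The assessed value; must be an element of `group`.
#' @param group Numeric vector containing `x`; at least 2 values must remain
#'   after excluding `x`.
#' @param sd_excludes_x See [cleaning_config()].
#' @return A non-negative number (possibly `Inf`).
#' @export
#' @examples
#' error_risk(10, c(1, 2, 3, 10))  # |10 - 2| / 1 = 8
error_risk <- function(x, group, sd_excludes_x = TRUE) {
  i <- match(x, group)
  if (is.na(i)) stop_tp("group must contain x")
  rest <- group[-i]
  if (length(rest) < 2) stop_tp("error risk undefined: group too small")
  m <- mean(rest)
  s <- if (sd_excludes_x) sd(rest) else sd(group)
  if (s == 0) {
    return(if (isTRUE(all.equal(x, m))) 0 else Inf)
  }
  abs(x - m) / s
}

# Vectorised leave-one-out risks for every element of x against the rest of
# its group. Returns NA for groups of size < 3 (step skipped).
loo_risk <- function(x, sd_excludes_x = TRUE) {
  n <- length(x)
  if (n < 3) return(rep(NA_real_, n))
  S <- sum(x)
  S2 <- sum(x^2)
  mean_excl <- (S - x) / (n - 1)
  if (sd_excludes_x) {
    v <- (S2 - x^2 - (n - 1) * mean_excl^2) / (n - 2)
    v[v < 0] <- 0                       # numerical fuzz
    s <- sqrt(v)
  } else {
    s <- rep(sqrt(max((S2 - S^2 / n) / (n - 1), 0)), n)
  }
  dev <- abs(x - mean_excl)
  risk <- ifelse(s > 0, dev / s,
                 ifelse(dev <= 1e-10 * pmax(abs(mean_excl), 1), 0, Inf))
  risk
}

#' Ratio of duplicated values within one dataset
#'
#' A record is a duplicate when its (species, trait, value) triple occurs
#' more than once within the dataset; each extra occurrence beyond the first
#' counts. The ratio is the duplicate count over the total record count.
#'
#' @param records Trait records of a single dataset.
#' @return A fraction in \[0, 1\].
#' @export
duplicate_ratio <- function(records) {
  if (nrow(records) == 0) return(0)
  key <- paste(records$species, records$trait, records$value, sep = "\r")
  sum(duplicated(key)) / nrow(records)
}

#' Collapse duplicated values in heavily duplicated datasets
#'
#' For every dataset whose [duplicate_ratio()] strictly exceeds the
#' threshold, each duplicated (species, trait, value) triple is collapsed to
#' a single record; datasets at or below the threshold are untouched (their
#' internal duplicates are assumed to be genuine repeat measurements).
#'
#' @param records Trait records (any number of datasets).
#' @param threshold Duplicated-value ratio above which a dataset is cleaned
#'   (default 0.30).
#' @return The surviving records; attribute `"removed"` is a tibble
#'   (`record_id`, `dataset_id`, `ratio`) of dropped duplicates.
#' @export
dedup_within_dataset <- function(records, threshold = 0.30) {
  key <- paste(records$dataset_id, records$species, records$trait,
               records$value, sep = "\r")
  is_extra <- duplicated(key)
  n_ds <- table(records$dataset_id)
  extras_ds <- tapply(is_extra, records$dataset_id, sum)
  ratio_ds <- extras_ds[names(n_ds)] / as.numeric(n_ds)
  flagged <- names(ratio_ds)[ratio_ds > threshold]
  drop <- is_extra & records$dataset_id %in% flagged
  removed <- tibble::tibble(record_id = records$record_id[drop],
                            dataset_id = records$dataset_id[drop],
                            ratio = unname(ratio_ds[records$dataset_id[drop]]))
  out <- records[!drop, ]
  attr(out, "removed") <- removed
  out
}

#' Species-level error-risk threshold as a function of record count
#'
#' Below `species_risk_n_low` records the threshold is `species_risk_min`;
#' above `species_risk_n_high` it is `species_risk_max`; between the two it
#' is interpolated linearly in the record count.
#'
#' @param n_records Number of records of the species (vectorised).
#' @param config A [cleaning_config()].
#' @return Numeric vector of thresholds.
#' @export
#' @examples
#' species_level_threshold(c(5, 20, 40))  # 2.25, 3.125, 4.0
species_level_threshold <- function(n_records, config = cleaning_config()) {
  lo <- config$species_risk_n_low
  hi <- config$species_risk_n_high
  a <- config$species_risk_min
  b <- config$species_risk_max
  if (a == b) return(rep(a, length(n_records)))   # incl. both infinite
  pmin(pmax(a + (b - a) * (n_records - lo) / (hi - lo), a), b)
}

#' Hierarchical error-risk cleaning of a trait table
#'
#' Applies, per trait and in strict order on the progressively cleaned
#' table: an optional within-dataset duplicate collapse; (1) a *global*
#' step removing records whose error risk against all observations of the
#' trait exceeds `global_risk`; (2) a *dataset* step in which, for species
#' present in at least `min_datasets_for_species_rule` distinct datasets,
#' per-dataset species means are screened against the other datasets' means
#' (threshold `dataset_species_risk`) and every record of the species in an
#' offending dataset is removed, while species in fewer datasets are
#' screened the same way at the genus level (threshold
#' `dataset_genus_risk`); and (3) a *species* step removing records whose
#' error risk against the species' own records exceeds the count-dependent
#' [species_level_threshold()], with species holding
#' `min_records_species_rule` records or fewer left untouched. Reference
#' groups too small for a step are skipped for that step, never an error.
#' Each step recomputes its statistics on the current survivors.
#'
#' @param records Trait records.
#' @param config A [cleaning_config()].
#' @param dedup Run the within-dataset duplicate collapse first
#'   (default `TRUE`).
#' @return An object of class `cleaning_result`: a list with `records` (the
#'   cleaned table), `report` (one row per removed record: `record_id`,
#'   `trait`, `step`, `risk`, `threshold`, `group_n`), and `summary`
#'   (per-step removal counts and the overall removed fraction).
#' @export
clean_traits <- function(records, config = cleaning_config(), dedup = TRUE) {
  stopifnot(inherits(config, "cleaning_config"))
  n_in <- nrow(records)
  report <- list()

  if (dedup) {
    records <- dedup_within_dataset(records, config$duplicate_ratio_threshold)
    rem <- attr(records, "removed")
    attr(records, "removed") <- NULL
    if (nrow(rem)) {
      report$duplicate <- tibble::tibble(
        record_id = rem$record_id, trait = NA_character_,
        step = "duplicate", risk = NA_real_, threshold = NA_real_,
        group_n = NA_integer_)
    }
  }

  # step 1: global, per trait ------------------------------------------------
  g <- records %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::mutate(.risk = loo_risk(.data$value, config$sd_excludes_x),
                  .gn = dplyr::n()) %>%
    dplyr::ungroup()
  drop <- !is.na(g$.risk) & g$.risk > config$global_risk
  report$global <- tibble::tibble(
    record_id = g$record_id[drop], trait = g$trait[drop], step = "global",
    risk = g$.risk[drop], threshold = config$global_risk,
    group_n = g$.gn[drop])
  records <- records[!records$record_id %in% g$record_id[drop], ]

  # step 2: dataset-level means ----------------------------------------------
  mfun <- if (config$dataset_means_log) function(v) mean(log(v)) else mean
  ds_counts <- records %>%
    dplyr::group_by(.data$trait, .data$species) %>%
    dplyr::summarise(n_ds = dplyr::n_distinct(.data$dataset_id),
                     .groups = "drop")
  records2 <- dplyr::left_join(records, ds_counts, by = c("trait", "species"))
  eligible_sp <- records2$n_ds >= config$min_datasets_for_species_rule

  # species rule
  sp_cells <- records2[eligible_sp, ] %>%
    dplyr::group_by(.data$trait, .data$species, .data$dataset_id) %>%
    dplyr::summarise(cell_mean = mfun(.data$value), .groups = "drop") %>%
    dplyr::group_by(.data$trait, .data$species) %>%
    dplyr::mutate(.risk = loo_risk(.data$cell_mean, config$sd_excludes_x),
                  .gn = dplyr::n()) %>%
    dplyr::ungroup() %>%
    dplyr::filter(!is.na(.data$.risk) &
                    .data$.risk > config$dataset_species_risk)

  # genus rule for under-sampled species
  gn_cells <- records2[!eligible_sp, ] %>%
    dplyr::group_by(.data$trait, .data$genus, .data$dataset_id) %>%
    dplyr::summarise(cell_mean = mfun(.data$value), .groups = "drop") %>%
    dplyr::group_by(.data$trait, .data$genus) %>%
    dplyr::mutate(.risk = loo_risk(.data$cell_mean, config$sd_excludes_x),
                  .gn = dplyr::n()) %>%
    dplyr::ungroup() %>%
    dplyr::filter(!is.na(.data$.risk) &
                    .data$.risk > config$dataset_genus_risk)

  hit_sp <- dplyr::inner_join(
    records2[eligible_sp, c("record_id", "trait", "species", "dataset_id")],
    sp_cells, by = c("trait", "species", "dataset_id"))
  hit_gn <- dplyr::inner_join(
    records2[!eligible_sp, c("record_id", "trait", "genus", "dataset_id")],
    gn_cells, by = c("trait", "genus", "dataset_id"))
  report$dataset <- dplyr::bind_rows(
    tibble::tibble(record_id = hit_sp$record_id, trait = hit_sp$trait,
                   step = "dataset_species", risk = hit_sp$.risk,
                   threshold = config$dataset_species_risk,
                   group_n = hit_sp$.gn),
    tibble::tibble(record_id = hit_gn$record_id, trait = hit_gn$trait,
                   step = "dataset_genus", risk = hit_gn$.risk,
                   threshold = config$dataset_genus_risk,
                   group_n = hit_gn$.gn))
  records <- records[!records$record_id %in% report$dataset$record_id, ]

  # step 3: species-level records --------------------------------------------
  s <- records %>%
    dplyr::group_by(.data$trait, .data$species) %>%
    dplyr::mutate(.n = dplyr::n(),
                  .risk = loo_risk(.data$value, config$sd_excludes_x)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(.thr = species_level_threshold(.data$.n, config))
  drop3 <- s$.n > config$min_records_species_rule &
    !is.na(s$.risk) & !is.na(s$.thr) & s$.risk > s$.thr
  report$species <- tibble::tibble(
    record_id = s$record_id[drop3], trait = s$trait[drop3], step = "species",
    risk = s$.risk[drop3], threshold = s$.thr[drop3], group_n = s$.n[drop3])
  records <- records[!records$record_id %in% s$record_id[drop3], ]

  report <- dplyr::bind_rows(report)
  summary <- report %>%
    dplyr::count(.data$step, name = "n_removed")
  out <- list(records = records, report = report,
              summary = list(per_step = summary,
                             n_in = n_in, n_out = nrow(records),
                             removed_fraction = (n_in - nrow(records)) / n_in))
  class(out) <- "cleaning_result"
  out
}

#' @export
print.cleaning_result <- function(x, ...) {
  cat("Trait cleaning:", x$summary$n_in, "records in,",
      x$summary$n_out, "out (",
      sprintf("%.2f%%", 100 * x$summary$removed_fraction), "removed)\n")
  if (nrow(x$summary$per_step)) print(x$summary$per_step)
  invisible(x)
}
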