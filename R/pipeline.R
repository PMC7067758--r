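#' Configuration for an end-to-end pipeline run
#'
#' Bundles stage toggles and per-stage options for [run_pipeline()]. Stages
#' run in the fixed order generate, clean, partition, scan, traitspace;
#' disabling a stage makes downstream stages read its outputs from
#' `outdir` (or from the explicit `records_path`/`sites_path`).
#'
#' @param outdir Output directory for all stage tables and the manifest.
#' @param stages Character vector of enabled stages.
#' @param synthetic A [synthetic_config()] for the generate stage.
#' @param cleaning A [cleaning_config()].
#' @param filter A [site_filter()] for the partition stage.
#' @param scan_min_species,scan_min_obs Scan eligibility thresholds.
#' @param scan_traits Traits to scan (default: all six core traits present).
#' @param pca_standardize Correlation-form PCA (default `TRUE`).
#' @param records_path,sites_path Input tables used when the generate (or
#'   clean) stage is disabled.
#' @param seed Integer seed recorded in the manifest and used to override
#'   the synthetic seed when supplied.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            stages = c("generate", "clean", "partition",
                                       "scan", "traitspace"),
                            synthetic = synthetic_config(),
                            cleaning = cleaning_config(),
                            filter = site_filter(),
                            scan_min_species = 3,
                            scan_min_obs = 2,
                            scan_traits = NULL,
                            pca_standardize = TRUE,
                            records_path = NULL,
                            sites_path = NULL,
                            seed = NULL) {
  stages <- match.arg(stages, c("generate", "clean", "partition", "scan",
                                "traitspace"), several.ok = TRUE)
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  structure(list(outdir = outdir, stages = stages, synthetic = synthetic,
                 cleaning = cleaning, filter = filter,
                 scan_min_species = scan_min_species,
                 scan_min_obs = scan_min_obs, scan_traits = scan_traits,
                 pca_standardize = pca_standardize,
                 records_path = records_path, sites_path = sites_path,
                 seed = seed %||% synthetic$seed),
            class = "pipeline_config")
}

#' Run the trait-variation pipeline
#'
#' Executes the enabled stages in order, writes every intermediate table to
#' `outdir` as delimited text, and returns a run manifest recording the
#' package version, seed, a hash of the configuration, and per-stage
#' in/out row counts. Reruns with the same configuration and seed produce
#' identical tables and manifests up to the timestamp.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  counts <- list()
  files <- character()
  emit <- function(tbl, name) {
    path <- file.path(outdir, name)
    write.csv(tbl, path, row.names = FALSE)
    files <<- c(files, name)
    path
  }

  records <- NULL
  sites <- NULL
  load_records <- function(stage) {
    path <- config$records_path %||% file.path(outdir, "records.csv")
    if (!file.exists(path)) {
      stop_tp("stage '", stage, "': input records not found at ", path)
    }
    read_trait_table(path)
  }
  load_sites <- function(stage) {
    path <- config$sites_path %||% file.path(outdir, "sites.csv")
    if (!file.exists(path)) {
      stop_tp("stage '", stage, "': site table not found at ", path)
    }
    read_site_table(path)
  }

  if ("generate" %in% stages) {
    db <- generate_database(config$synthetic)
    records <- db$records
    sites <- db$sites
    emit(records, "records.csv")
    emit(sites, "sites.csv")
    emit(db$truth$fractions, "truth_fractions.csv")
    emit(db$truth$record_flags, "truth_flags.csv")
    counts$generate <- list(n_out = nrow(records))
  }

  cleaned <- NULL
  if ("clean" %in% stages) {
    if (is.null(records)) records <- load_records("clean")
    res <- clean_traits(records, config$cleaning)
    cleaned <- res$records
    emit(cleaned, "cleaned.csv")
    emit(res$report, "cleaning_report.csv")
    counts$clean <- list(n_in = res$summary$n_in, n_out = res$summary$n_out,
                         removed_fraction = res$summary$removed_fraction)
  } else {
    path <- file.path(outdir, "cleaned.csv")
    if (file.exists(path)) cleaned <- read_trait_table(path)
  }
  analysis_records <- cleaned %||% records

  if ("partition" %in% stages) {
    if (is.null(analysis_records)) analysis_records <- load_records("partition")
    part <- partition_by_site(analysis_records, config$filter)
    emit(part$per_site, "varcomp_per_site.csv")
    emit(part$by_trait, "varcomp_by_trait.csv")
    emit(tibble::as_tibble(as.list(part$grand_mean)), "varcomp_grand_mean.csv")
    counts$partition <- list(n_in = nrow(analysis_records),
                             n_out = nrow(part$per_site))
  }

  if ("scan" %in% stages) {
    if (is.null(analysis_records)) analysis_records <- load_records("scan")
    if (is.null(sites)) sites <- load_sites("scan")
    steps <- scan_all_sites(analysis_records, sites,
                            min_species = config$scan_min_species,
                            min_obs_per_species = config$scan_min_obs,
                            traits = config$scan_traits)
    emit(steps, "scan_steps.csv")
    bins <- dplyr::bind_rows(lapply(split(steps, steps$trait), function(s) {
      dplyr::mutate(bin_and_interval(s, "scale_km", 5),
                    trait = s$trait[1], .before = 1)
    }))
    emit(bins, "scan_bins.csv")
    signif <- dplyr::bind_rows(lapply(split(steps, steps$trait), function(s) {
      dplyr::mutate(test_bin_significance(s, "scale_km"),
                    trait = s$trait[1], .before = 1)
    }))
    emit(signif, "scan_significance.csv")
    bps <- dplyr::bind_rows(lapply(split(steps, steps$trait), function(s) {
      s <- s[s$scale_km > 0, ]
      if (nrow(s) < 6) return(NULL)
      f <- fit_breakpoint(log10(s$scale_km), s$f_within)
      tibble::tibble(trait = s$trait[1], psi_log10_km = f$psi,
                     psi_km = 10^f$psi, slope_left = f$slope_left,
                     slope_right = f$slope_right, rss = f$rss,
                     converged = f$converged)
    }))
    emit(bps, "scan_breakpoints.csv")
    counts$scan <- list(n_in = nrow(analysis_records), n_out = nrow(steps))
  }

  if ("traitspace" %in% stages) {
    if (is.null(analysis_records)) analysis_records <- load_records("traitspace")
    traits_present <- intersect(setdiff(TRAIT_LEVELS, "SSD"),
                                unique(analysis_records$trait))
    M <- build_species_matrix(analysis_records, traits_present)
    pca <- run_pca(M, standardize = config$pca_standardize)
    emit(tibble::as_tibble(pca$loadings, rownames = "trait"),
         "pca_loadings.csv")
    emit(tibble::as_tibble(pca$scores, rownames = "species"),
         "pca_scores.csv")
    emit(tibble::as_tibble(pca$contributions, rownames = "trait"),
         "pca_contributions.csv")
    emit(tibble::tibble(axis = colnames(pca$loadings),
                        explained = pca$explained), "pca_explained.csv")
    counts$traitspace <- list(n_in = nrow(analysis_records),
                              n_species = nrow(M))
  }

  cfg_hash <- rlang::hash(config[setdiff(names(config), "outdir")])
  manifest <- list(package = "traitpart",
                   version = as.character(utils::packageVersion("traitpart")),
                   seed = config$seed,
                   config_hash = cfg_hash,
                   stages = stages,
                   counts = counts,
                   files = files,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
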