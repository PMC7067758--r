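#' Configuration for the synthetic trait-database generator
#'
#' Builds a validated configuration for [generate_database()] and
#' [generate_sites()]. The generator emulates a multi-contributor plant trait
#' database: log-normal traits with a three-level variance hierarchy
#' (functional group, species, within-species residual), two planted
#' trait-space factors (a plant-size axis and a resource-economics axis)
#' injected into the species-level effects, spatially clustered collection
#' sites with distance-decaying species turnover, and injected exact
#' duplicates and multiplicative outliers. Because the structure is planted,
#' every downstream stage (cleaning, variance partitioning, spatial scan,
#' PCA) can be tested against known ground truth.
#'
#' @param n_functional_groups Number of functional groups (default 4,
#'   mirroring deciduous shrubs, evergreen shrubs, graminoids and forbs).
#' @param n_species Total number of species, assigned to groups round-robin.
#' @param n_sites Number of collection sites.
#' @param n_site_clusters Number of spatial clusters the sites fall into.
#' @param cluster_radius_km Maximum pairwise great-circle spread of sites
#'   within one cluster (km).
#' @param inter_cluster_km Minimum great-circle separation between sites of
#'   different clusters (km).
#' @param obs_per_species_site Trait observations per species per occupied
#'   site (per trait).
#' @param trait_names Character vector of traits to simulate (subset of the
#'   canonical seven; default the six core traits, excluding SSD).
#' @param mu_log Named per-trait grand mean on the log scale.
#' @param var_group,var_species,var_within Named per-trait variance
#'   components on the log scale. `var_species` is the species-level variance
#'   *beyond* the planted factors; the total species-level variance is
#'   `var_species + rowSums(factor_loadings^2)`.
#' @param factor_loadings Trait-by-2 matrix of loadings planting the size
#'   axis (column 1) and economics axis (column 2) into species effects.
#' @param turnover_rate Distance-decay rate (per km) of species-site
#'   occupancy probability: `p = exp(-turnover_rate * d_home_km)`.
#' @param outlier_rate Fraction of records multiplied by `outlier_factor`
#'   (emulating unit errors).
#' @param outlier_factor Multiplier applied to outlier records.
#' @param duplicate_rate Fraction of records copied verbatim within the same
#'   dataset (emulating within-dataset duplicated values).
#' @param n_datasets Number of contributing datasets; sites are assigned to
#'   datasets round-robin.
#' @param mat_range Range (degrees C) for site mean annual temperature.
#' @param class_temp_range Range (degrees C) for the site temperature used in
#'   species temperature classes; the default spans the class thresholds at
#'   -1 and +1.
#' @param cluster_lat Latitude (degrees) of the cluster-centre parallel.
#' @param seed Integer seed; fully determines the generated database.
#'
#' @return An object of class `synthetic_config` (a named list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_species = 12, n_sites = 6, n_site_clusters = 2,
#'                         seed = 1)
#' sites <- generate_sites(cfg)
synthetic_config <- function(n_functional_groups = 4,
                             n_species = 80,
                             n_sites = 40,
                             n_site_clusters = 4,
                             cluster_radius_km = 30,
                             inter_cluster_km = 1500,
                             obs_per_species_site = 4,
                             trait_names = setdiff(TRAIT_LEVELS, "SSD"),
                             mu_log = NULL,
                             var_group = NULL,
                             var_species = NULL,
                             var_within = NULL,
                             factor_loadings = NULL,
                             turnover_rate = 0.002,
                             outlier_rate = 0.02,
                             outlier_factor = 50,
                             duplicate_rate = 0.02,
                             n_datasets = 80,
                             mat_range = c(-8, 4),
                             class_temp_range = c(-3, 3),
                             cluster_lat = 68,
                             seed = 42) {
  nt <- length(trait_names)
  if (nt < 1) stop_tp("at least one trait is required")
  if (!all(trait_names %in% TRAIT_LEVELS)) {
    stop_tp("unknown trait names: ",
            paste(setdiff(trait_names, TRAIT_LEVELS), collapse = ", "))
  }

  default_mu <- c(plant_height = -1.6, leaf_area = 5.7, seed_mass = -0.7,
                  LMA = 4.4, leaf_nitrogen = 3.0, LDMC = -1.4, SSD = -0.9)
  mu_log <- expand_trait_param(mu_log %||% default_mu[trait_names],
                               trait_names, "mu_log")
  var_group <- expand_trait_param(var_group %||% 0.15, trait_names, "var_group")
  var_species <- expand_trait_param(var_species %||% 0.10, trait_names,
                                    "var_species")
  var_within <- expand_trait_param(var_within %||% 0.15, trait_names,
                                   "var_within")

  if (is.null(factor_loadings)) {
    L0 <- rbind(plant_height = c(0.45, 0.00),
                leaf_area    = c(0.40, -0.12),
                seed_mass    = c(0.42, 0.00),
                LMA          = c(0.00, 0.42),
                leaf_nitrogen = c(0.00, -0.45),
                LDMC         = c(0.10, 0.40),
                SSD          = c(0.08, 0.38))
    factor_loadings <- L0[trait_names, , drop = FALSE]
  } else {
    factor_loadings <- as.matrix(factor_loadings)
    if (nrow(factor_loadings) != nt || ncol(factor_loadings) != 2) {
      stop_tp("factor_loadings must be a ", nt, " x 2 matrix")
    }
    rownames(factor_loadings) <- trait_names
  }

  cfg <- list(n_functional_groups = n_functional_groups,
              n_species = n_species, n_sites = n_sites,
              n_site_clusters = n_site_clusters,
              cluster_radius_km = cluster_radius_km,
              inter_cluster_km = inter_cluster_km,
              obs_per_species_site = obs_per_species_site,
              trait_names = trait_names, mu_log = mu_log,
              var_group = var_group, var_species = var_species,
              var_within = var_within, factor_loadings = factor_loadings,
              turnover_rate = turnover_rate, outlier_rate = outlier_rate,
              outlier_factor = outlier_factor,
              duplicate_rate = duplicate_rate, n_datasets = n_datasets,
              mat_range = mat_range, class_temp_range = class_temp_range,
              cluster_lat = cluster_lat, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

expand_trait_param <- function(x, trait_names, what) {
  nt <- length(trait_names)
  if (length(x) == 1 && is.null(names(x))) x <- rep(x, nt)
  if (is.null(names(x))) {
    if (length(x) != nt) stop_tp(what, " must have length 1 or ", nt)
    names(x) <- trait_names
  }
  if (!all(trait_names %in% names(x))) {
    stop_tp(what, " missing entries for: ",
            paste(setdiff(trait_names, names(x)), collapse = ", "))
  }
  x[trait_names]
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_species < n_functional_groups) {
      stop_tp("n_species must be >= n_functional_groups")
    }
    if (n_sites < n_site_clusters || n_site_clusters < 1) {
      stop_tp("need n_sites >= n_site_clusters >= 1")
    }
    if (any(c(var_group, var_species, var_within) < 0)) {
      stop_tp("variance components must be >= 0")
    }
    rates <- c(outlier_rate, duplicate_rate)
    if (any(rates < 0 | rates > 1)) stop_tp("rates must lie in [0, 1]")
    if (n_site_clusters > 1 && cluster_radius_km >= inter_cluster_km / 2) {
      stop_tp("infeasible geometry: cluster_radius_km must be < ",
              "inter_cluster_km / 2")
    }
    if (turnover_rate < 0) stop_tp("turnover_rate must be >= 0")
  })
  invisible(cfg)
}

#' True variance fractions implied by a synthetic configuration
#'
#' @param config A [synthetic_config()].
#' @return A tibble with one row per trait and columns `f_group`,
#'   `f_species`, `f_within` summing to 1.
#' @export
true_fractions <- function(config) {
  L2 <- rowSums(config$factor_loadings^2)
  vs <- config$var_species + L2
  tot <- config$var_group + vs + config$var_within
  tibble::tibble(trait = config$trait_names,
                 f_group = unname(config$var_group / tot),
                 f_species = unname(vs / tot),
                 f_within = unname(config$var_within / tot))
}

#' Generate clustered collection sites
#'
#' Places `n_site_clusters` cluster centres along a single parallel at
#' `cluster_lat`, separated so that sites of different clusters are at least
#' `inter_cluster_km` apart, then scatters sites uniformly in a disc of
#' diameter `cluster_radius_km` around their centre (so the within-cluster
#' great-circle spread never exceeds `cluster_radius_km`). Each site carries
#' a mean annual temperature and a class temperature drawn uniformly from
#' the configured ranges.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `site_id`, `latitude`, `longitude`,
#'   `cluster`, `mean_annual_temperature`, `class_temperature`.
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- config$n_site_clusters
  n <- config$n_sites
  lat0 <- config$cluster_lat
  R <- 6371.0

  if (k > 1) {
    # Longitude spacing whose great-circle distance along the parallel is
    # inter_cluster_km + cluster_radius_km, leaving room for disc offsets.
    d0 <- config$inter_cluster_km + config$cluster_radius_km
    s <- sin(d0 / (2 * R)) / cos(lat0 * pi / 180)
    if (s >= 1) stop_tp("infeasible geometry: clusters do not fit at this latitude")
    dlon <- 2 * asin(s) * 180 / pi
    if ((k - 1) * dlon > 180) {
      stop_tp("infeasible geometry: too many clusters for the requested separation")
    }
    centre_lon <- (seq_len(k) - (k + 1) / 2) * dlon
  } else {
    centre_lon <- 0
  }
  centre_lat <- rep(lat0, k)

  cluster <- sort(rep_len(seq_len(k), n))
  theta <- runif(n, 0, 2 * pi)
  rad <- (config$cluster_radius_km / 2) * sqrt(runif(n))
  km_per_deg <- pi * R / 180
  lat <- centre_lat[cluster] + (rad * sin(theta)) / km_per_deg
  lon <- centre_lon[cluster] +
    (rad * cos(theta)) / (km_per_deg * cos(centre_lat[cluster] * pi / 180))

  tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n)),
    latitude = lat,
    longitude = lon,
    cluster = cluster,
    mean_annual_temperature = runif(n, config$mat_range[1], config$mat_range[2]),
    class_temperature = runif(n, config$class_temp_range[1],
                              config$class_temp_range[2]))
}

#' Generate a synthetic trait database with known ground truth
#'
#' Simulates a long-format trait observation table on top of the site layout
#' of [generate_sites()]. The log value of every clean record is
#' `mu_log[t] + a_g + b_s + e`, with group effects
#' `a_g ~ N(0, var_group[t])`, species effects
#' `b_s ~ N(0, var_species[t]) + factor_loadings[t, ] %*% z_s` for standard
#' normal factor scores `z_s`, and residuals `e ~ N(0, var_within[t])`.
#' Values are exported on the natural scale (exponentiated, strictly
#' positive). Species occupy sites with probability decaying with distance
#' from a random home site; outlier records are multiplied by
#' `outlier_factor`, and duplicate records are copied verbatim within their
#' dataset. All injected artefacts are flagged in the ground truth.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_database` with elements:
#'   * `records`: tibble of trait records (one row per measurement) with
#'     columns `record_id`, `species`, `genus`, `functional_group`,
#'     `dataset_id`, `site_id`, `latitude`, `longitude`, `trait`, `value`,
#'     `units`;
#'   * `sites`: the site table;
#'   * `truth`: list with `fractions` (true per-trait variance fractions),
#'     `factor_scores`, `record_flags` (`is_outlier`, `is_duplicate`),
#'     `occupancy` (long species-site table), and `species` metadata;
#'   * `config`: the configuration used.
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sites <- generate_sites(config)     # seeds the RNG stream
  nt <- length(config$trait_names)
  ns <- config$n_species
  ng <- config$n_functional_groups

  group_of <- rep_len(seq_len(ng), ns)
  group_names <- rep_len(FUNCTIONAL_GROUPS, ng)
  if (ng > length(FUNCTIONAL_GROUPS)) {
    group_names <- paste0("group_", seq_len(ng))
  }
  # genera: blocks of up to 3 species within one functional group
  genus_idx <- stats::ave(seq_len(ns), group_of,
                          FUN = function(i) ceiling(seq_along(i) / 3))
  species_tbl <- tibble::tibble(
    species = sprintf("Species_%03d", seq_len(ns)),
    genus = sprintf("Genus_%02d_%02d", group_of, genus_idx),
    functional_group = group_names[group_of])

  # effects (fixed RNG order: group, factor scores, species, homes, occupancy)
  A <- matrix(rnorm(ng * nt), ng, nt) %*% diag(sqrt(config$var_group), nt)
  Z <- matrix(rnorm(ns * 2), ns, 2)
  B <- matrix(rnorm(ns * nt), ns, nt) %*% diag(sqrt(config$var_species), nt) +
    Z %*% t(config$factor_loadings)

  home <- sample.int(config$n_sites, ns, replace = TRUE)
  D <- site_distance_matrix(sites)
  p_occ <- exp(-config$turnover_rate * D[home, , drop = FALSE])
  occ <- matrix(runif(ns * config$n_sites) < p_occ, ns, config$n_sites)
  occ[cbind(seq_len(ns), home)] <- TRUE

  pairs <- which(occ, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  m <- config$obs_per_species_site
  ind_species <- rep(pairs[, 1], each = m)
  ind_site <- rep(pairs[, 2], each = m)
  n_ind <- length(ind_species)

  rec_species <- rep(ind_species, times = nt)
  rec_site <- rep(ind_site, times = nt)
  rec_trait_idx <- rep(seq_len(nt), each = n_ind)
  n_rec <- length(rec_species)

  e <- rnorm(n_rec, 0, sqrt(config$var_within)[rec_trait_idx])
  log_value <- config$mu_log[rec_trait_idx] +
    A[cbind(group_of[rec_species], rec_trait_idx)] +
    B[cbind(rec_species, rec_trait_idx)] + e

  unit_of <- c(plant_height = "m", leaf_area = "mm2", seed_mass = "mg",
               LMA = "g m-2", leaf_nitrogen = "mg g-1", LDMC = "g g-1",
               SSD = "mg mm-3")
  # datasets emulate many independent contributors: each record belongs to
  # one of n_datasets parcels, so species x dataset cells stay small
  dataset_of_rec <- paste0("D", sample.int(config$n_datasets, n_rec,
                                           replace = TRUE))

  records <- tibble::tibble(
    record_id = sprintf("R%07d", seq_len(n_rec)),
    species = species_tbl$species[rec_species],
    genus = species_tbl$genus[rec_species],
    functional_group = species_tbl$functional_group[rec_species],
    dataset_id = dataset_of_rec,
    site_id = sites$site_id[rec_site],
    latitude = sites$latitude[rec_site],
    longitude = sites$longitude[rec_site],
    trait = config$trait_names[rec_trait_idx],
    value = exp(unname(log_value)),
    units = unname(unit_of[config$trait_names[rec_trait_idx]]))

  is_outlier <- runif(n_rec) < config$outlier_rate
  records$value[is_outlier] <- records$value[is_outlier] * config$outlier_factor

  dup_src <- which(runif(n_rec) < config$duplicate_rate)
  if (length(dup_src)) {
    dups <- records[dup_src, ]
    dups$record_id <- sprintf("R%07d", n_rec + seq_along(dup_src))
    records <- dplyr::bind_rows(records, dups)
  }
  flags <- tibble::tibble(
    record_id = records$record_id,
    is_outlier = c(is_outlier, is_outlier[dup_src]),
    is_duplicate = c(rep(FALSE, n_rec), rep(TRUE, length(dup_src))))

  occupancy <- tibble::tibble(
    species = species_tbl$species[pairs[, 1]],
    site_id = sites$site_id[pairs[, 2]])

  truth <- list(fractions = true_fractions(config),
                factor_scores = tibble::tibble(species = species_tbl$species,
                                               size_score = Z[, 1],
                                               econ_score = Z[, 2]),
                record_flags = flags,
                occupancy = occupancy,
                species = species_tbl)
  out <- list(records = records, sites = sites, truth = truth, config = config)
  class(out) <- "synthetic_database"
  out
}

#' @export
print.synthetic_database <- function(x, ...) {
  cat("Synthetic trait database:",
      nrow(x$records), "records,",
      dplyr::n_distinct(x$records$species), "species,",
      nrow(x$sites), "sites,",
      length(x$config$trait_names), "traits\n")
  invisible(x)
}

site_distance_matrix <- function(sites) {
  xy <- cbind(sites$longitude, sites$latitude)
  geosphere::distm(xy, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371000)
  }) / 1000
}

#' Write a synthetic database to delimited text files
#'
#' Emits `records.csv`, `sites.csv`, the ground-truth sidecars
#' (`truth_fractions.csv`, `truth_flags.csv`, `truth_factor_scores.csv`,
#' `truth_occupancy.csv`) and the configuration as `config.yaml`.
#'
#' @param db A `synthetic_database` from [generate_database()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_database <- function(db, dir) {
  stopifnot(inherits(db, "synthetic_database"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "records.csv"),
             sites = file.path(dir, "sites.csv"),
             fractions = file.path(dir, "truth_fractions.csv"),
             flags = file.path(dir, "truth_flags.csv"),
             scores = file.path(dir, "truth_factor_scores.csv"),
             occupancy = file.path(dir, "truth_occupancy.csv"),
             config = file.path(dir, "config.yaml"))
  write_trait_table(db$records, paths["records"])
  write.csv(db$sites, paths["sites"], row.names = FALSE)
  write.csv(db$truth$fractions, paths["fractions"], row.names = FALSE)
  write.csv(db$truth$record_flags, paths["flags"], row.names = FALSE)
  write.csv(db$truth$factor_scores, paths["scores"], row.names = FALSE)
  write.csv(db$truth$occupancy, paths["occupancy"], row.names = FALSE)
  write_synthetic_config(db$config, paths["config"])
  invisible(paths)
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [synthetic_config()].
#' @param path File path.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` returns a `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  x$factor_loadings <- list(size = unname(config$factor_loadings[, 1]),
                            economics = unname(config$factor_loadings[, 2]))
  x$mu_log <- as.list(config$mu_log)
  x$var_group <- as.list(config$var_group)
  x$var_species <- as.list(config$var_species)
  x$var_within <- as.list(config$var_within)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- yaml::read_yaml(path)
  L <- cbind(x$factor_loadings$size, x$factor_loadings$economics)
  synthetic_config(
    n_functional_groups = x$n_functional_groups, n_species = x$n_species,
    n_sites = x$n_sites, n_site_clusters = x$n_site_clusters,
    cluster_radius_km = x$cluster_radius_km,
    inter_cluster_km = x$inter_cluster_km,
    obs_per_species_site = x$obs_per_species_site,
    trait_names = x$trait_names,
    mu_log = unlist(x$mu_log), var_group = unlist(x$var_group),
    var_species = unlist(x$var_species), var_within = unlist(x$var_within),
    factor_loadings = L, turnover_rate = x$turnover_rate,
    outlier_rate = x$outlier_rate, outlier_factor = x$outlier_factor,
    duplicate_rate = x$duplicate_rate, n_datasets = x$n_datasets,
    mat_range = unlist(x$mat_range),
    class_temp_range = unlist(x$class_temp_range),
    cluster_lat = x$cluster_lat, seed = x$seed)
}
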