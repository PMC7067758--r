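# Small generator configurations shared across tests.

# compact clustered world for spatial tests
small_scan_config <- function(seed, traits = c("plant_height", "leaf_nitrogen")) {
  synthetic_config(
    n_functional_groups = 4, n_species = 24, n_sites = 12,
    n_site_clusters = 3, cluster_radius_km = 25, inter_cluster_km = 2000,
    obs_per_species_site = 3, trait_names = traits,
    outlier_rate = 0, duplicate_rate = 0, n_datasets = 10, seed = seed)
}

# balanced single-site design: 4 groups x 25 species x n obs, planted
# fractions (0.25, 0.50, 0.25), no factor structure
balanced_config <- function(seed, obs = 20) {
  synthetic_config(
    n_functional_groups = 4, n_species = 100, n_sites = 1,
    n_site_clusters = 1, obs_per_species_site = obs,
    trait_names = "plant_height",
    var_group = 0.25, var_species = 0.5, var_within = 0.25,
    factor_loadings = matrix(0, 1, 2), turnover_rate = 0,
    outlier_rate = 0, duplicate_rate = 0, seed = seed)
}

# trait-space world: the planted two-factor structure dominates the
# species level (weak functional-group noise), as in species-mean
# ordinations where two axes carry most of the variance
traitspace_config <- function(seed) {
  synthetic_config(var_group = 0.05, n_species = 120, seed = seed)
}

# hand-built trait records
make_records <- function(values, species = "Sp_a", genus = "Gen_a",
                         functional_group = "forb", dataset_id = "D1",
                         site_id = "S1", trait = "plant_height",
                         id_prefix = "r") {
  n <- length(values)
  tibble::tibble(
    record_id = paste0(id_prefix, seq_len(n)),
    species = rep_len(species, n), genus = rep_len(genus, n),
    functional_group = rep_len(functional_group, n),
    dataset_id = rep_len(dataset_id, n), site_id = rep_len(site_id, n),
    latitude = NA_real_, longitude = NA_real_,
    trait = rep_len(trait, n), value = values, units = "m")
}

make_sites <- function(site_id, latitude, longitude, mat = 0, class_temp = 0) {
  tibble::tibble(site_id = site_id, latitude = latitude,
                 longitude = longitude,
                 mean_annual_temperature = rep_len(mat, length(site_id)),
                 class_temperature = rep_len(class_temp, length(site_id)))
}

# independent closed-form expected-mean-squares oracle for balanced nested
# designs (groups / species / residual), used to check the REML fits
ems_oracle <- function(y, species, group) {
  sp <- factor(species)
  gr <- factor(group)
  n <- as.numeric(table(sp))
  stopifnot(length(unique(n)) == 1)
  n <- n[1]
  m_s <- tapply(y, sp, mean)
  g_of_s <- tapply(as.character(gr), sp, function(v) v[1])
  s_per_g <- table(g_of_s)
  stopifnot(length(unique(as.numeric(s_per_g))) == 1)
  s <- as.numeric(s_per_g)[1]
  g <- length(s_per_g)
  m_g <- tapply(m_s, g_of_s, mean)
  ssw <- sum((y - m_s[as.character(sp)])^2)
  msw <- ssw / (g * s * (n - 1))
  mss <- n * sum((m_s - m_g[g_of_s])^2) / (g * (s - 1))
  msg <- s * n * sum((m_g - mean(m_s))^2) / (g - 1)
  comp <- c(group = (msg - mss) / (s * n), species = (mss - msw) / n,
            within = msw)
  comp
}

# brute-force haversine, written independently of the package
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371) {
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * R * asin(pmin(sqrt(a), 1))
}
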