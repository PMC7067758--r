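#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.195
haversine_km <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) {
    all(is.finite(lat)) && all(is.finite(lon)) &&
      all(lat >= -90 & lat <= 90) && all(lon >= -180 & lon <= 180)
  }
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) {
    stop_tp("invalid coordinates: latitude in [-90, 90], ",
            "longitude in [-180, 180]")
  }
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                      r = 6371000)) / 1000
}

#' Scan eligibility of sites
#'
#' A site is eligible when, for at least one of the analysed traits, it
#' holds at least `min_species` species each having at least
#' `min_obs_per_species` observations of that trait at the site.
#'
#' @param records Trait records.
#' @param min_species Minimum qualifying species per site (default 3).
#' @param min_obs_per_species Minimum observations per species per trait
#'   (default 2).
#' @param traits Traits to consider (default: all present).
#' @return Character vector of eligible `site_id`s.
#' @export
eligible_sites <- function(records, min_species = 3,
                           min_obs_per_species = 2, traits = NULL) {
  if (!is.null(traits)) records <- records[records$trait %in% traits, ]
  counts <- records %>%
    dplyr::count(.data$site_id, .data$trait, .data$species, name = "n_obs") %>%
    dplyr::filter(.data$n_obs >= min_obs_per_species) %>%
    dplyr::count(.data$site_id, .data$trait, name = "n_species") %>%
    dplyr::filter(.data$n_species >= min_species)
  sort(unique(counts$site_id))
}

#' Geographic-scale accumulation scan from one start site
#'
#' Starting from `start_site`, the scan begins with the start site alone
#' (step 0, geographic scale 0), then repeatedly adds the nearest
#' not-yet-included eligible site and refits the nested variance
#' decomposition per trait on the pooled records, until all eligible sites
#' are included (the biome scale). The geographic scale of a step is the
#' great-circle distance from the start site to the most distant included
#' site; richness is the number of unique species with trait measurements
#' in the included set. Distance ties are broken by lexicographic
#' `site_id`.
#'
#' @param records Trait records.
#' @param sites Site table with coordinates.
#' @param start_site `site_id` of the starting site (must be eligible).
#' @param min_species,min_obs_per_species Eligibility thresholds, see
#'   [eligible_sites()].
#' @param traits Traits to analyse (default: all present in `records`).
#' @param scale Analysis scale for the variance fits (default `"log"`).
#' @param nearest `"start"` (default) measures candidate distances from the
#'   start site; `"set"` uses the minimum distance to any included site
#'   while still reporting the scale as distance from the start.
#' @return Tibble with one row per step x trait: `start_site_id`,
#'   `step_index`, `scale_km`, `richness`, `trait`, `f_group`, `f_species`,
#'   `f_within`, `f_among` (group + species), `n_obs`, `n_species`,
#'   `converged`.
#' @export
scan_from_site <- function(records, sites, start_site,
                           min_species = 3, min_obs_per_species = 2,
                           traits = NULL, scale = "log",
                           nearest = c("start", "set")) {
  nearest <- match.arg(nearest)
  traits <- traits %||% sort(unique(records$trait))
  records <- records[records$trait %in% traits, ]
  check_site_coverage(records, sites)
  elig <- eligible_sites(records, min_species, min_obs_per_species, traits)
  if (!start_site %in% elig) {
    stop_tp("start site ", start_site, " is not eligible")
  }
  sites_e <- sites[sites$site_id %in% elig, ]
  sites_e <- sites_e[order(sites_e$site_id), ]
  i0 <- which(sites_e$site_id == start_site)
  d_start <- haversine_km(sites_e$latitude[i0], sites_e$longitude[i0],
                          sites_e$latitude, sites_e$longitude)

  n_e <- nrow(sites_e)
  if (nearest == "start") {
    ord <- order(d_start, sites_e$site_id)
  } else {
    D <- outer(seq_len(n_e), seq_len(n_e), function(i, j) {
      haversine_km(sites_e$latitude[i], sites_e$longitude[i],
                   sites_e$latitude[j], sites_e$longitude[j])
    })
    ord <- i0
    remaining <- setdiff(seq_len(n_e), i0)
    while (length(remaining)) {
      dmin <- apply(D[ord, remaining, drop = FALSE], 2, min)
      pick <- remaining[order(dmin, sites_e$site_id[remaining])][1]
      ord <- c(ord, pick)
      remaining <- setdiff(remaining, pick)
    }
  }
  site_seq <- sites_e$site_id[ord]

  # pre-split per trait for speed
  if (scale == "log" && any(records$value <= 0)) {
    stop_tp("log scale requires strictly positive values")
  }
  by_trait <- split(
    data.frame(y = if (scale == "log") log(records$value) else records$value,
               species = records$species,
               group = records$functional_group,
               site_id = records$site_id,
               stringsAsFactors = FALSE),
    records$trait)

  steps <- vector("list", length(site_seq))
  for (k in seq_along(site_seq)) {
    included <- site_seq[seq_len(k)]
    scale_km <- if (k == 1) 0 else max(d_start[ord[seq_len(k)]])
    rec_k <- records[records$site_id %in% included, ]
    richness <- dplyr::n_distinct(rec_k$species)
    rows <- lapply(names(by_trait), function(tr) {
      dt <- by_trait[[tr]]
      dt <- dt[dt$site_id %in% included, ]
      if (nrow(dt) == 0) return(NULL)
      fit <- fit_vc_vectors(dt$y, dt$species, dt$group)
      tibble::tibble(start_site_id = start_site, step_index = k - 1L,
                     scale_km = scale_km, richness = richness, trait = tr,
                     f_group = fit$fractions[["group"]],
                     f_species = fit$fractions[["species"]],
                     f_within = fit$fractions[["within"]],
                     f_among = fit$fractions[["group"]] +
                       fit$fractions[["species"]],
                     n_obs = fit$n_obs, n_species = fit$n_species,
                     converged = fit$converged)
    })
    steps[[k]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(steps)
}

#' Run the accumulation scan from every eligible start site
#'
#' @inheritParams scan_from_site
#' @return Row-bound [scan_from_site()] tables over all eligible starts.
#' @export
scan_all_sites <- function(records, sites, min_species = 3,
                           min_obs_per_species = 2, traits = NULL,
                           scale = "log", nearest = "start") {
  traits <- traits %||% sort(unique(records$trait))
  elig <- eligible_sites(records, min_species, min_obs_per_species, traits)
  dplyr::bind_rows(lapply(elig, function(s) {
    scan_from_site(records, sites, s, min_species, min_obs_per_species,
                   traits, scale, nearest)
  }))
}

#' Bin scan steps and compute spread intervals
#'
#' Groups scan steps into half-open bins `[k*width, (k+1)*width)` along the
#' chosen axis and summarises, per bin and per source of variation (within
#' vs. among species), the mean fraction and the empirical 2.5/97.5
#' percentiles of the step values. Bins holding fewer than 3 steps are
#' flagged interval-undefined.
#'
#' @param steps A scan table (typically filtered to one trait).
#' @param axis `"scale_km"` or `"richness"`.
#' @param width Bin width (5 km and 1 species are the conventional choices).
#' @return Tibble with columns `bin`, `bin_center`, `source`, `mean`,
#'   `lower95`, `upper95`, `n_steps`, `interval_defined`.
#' @export
bin_and_interval <- function(steps, axis = c("scale_km", "richness"),
                             width = if (axis[1] == "scale_km") 5 else 1) {
  axis <- match.arg(axis)
  x <- steps[[axis]]
  bin <- floor(x / width)
  long <- tibble::tibble(bin = rep(bin, 2),
                         source = rep(c("within", "among"), each = nrow(steps)),
                         fraction = c(steps$f_within, steps$f_among))
  long %>%
    dplyr::group_by(.data$bin, .data$source) %>%
    dplyr::summarise(mean = mean(.data$fraction),
                     lower95 = quantile(.data$fraction, 0.025, names = FALSE),
                     upper95 = quantile(.data$fraction, 0.975, names = FALSE),
                     n_steps = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(bin_center = (.data$bin + 0.5) * width,
                  interval_defined = .data$n_steps >= 3) %>%
    dplyr::select("bin", "bin_center", "source", "mean", "lower95",
                  "upper95", "n_steps", "interval_defined")
}

#' Test within- vs among-species differences in equal bins
#'
#' Splits the axis into `n_bins` equal-width bins (on the log10 axis by
#' default, since scale analyses are presented on a log scale; axis values
#' that are not positive cannot be placed on a log axis and are excluded)
#' and, within each bin, fits a linear model of the step-level fraction on
#' the source indicator (within vs. among species). The two-sided p-value
#' of the source coefficient flags bins where the two sources do not differ
#' significantly.
#'
#' @param steps A scan table (typically one trait).
#' @param axis `"scale_km"` or `"richness"`.
#' @param n_bins Number of equal bins (default 10).
#' @param alpha Significance threshold (default 0.05).
#' @param log_axis Bin on log10(axis) (default `TRUE`).
#' @return Tibble with `bin`, `lower`, `upper` (axis units), `n_steps`,
#'   `p_value`, `significant`, `testable`.
#' @export
test_bin_significance <- function(steps, axis = c("scale_km", "richness"),
                                  n_bins = 10, alpha = 0.05,
                                  log_axis = TRUE) {
  axis <- match.arg(axis)
  x <- steps[[axis]]
  keep <- if (log_axis) x > 0 else rep(TRUE, length(x))
  steps <- steps[keep, ]
  ax <- if (log_axis) log10(steps[[axis]]) else steps[[axis]]
  rng <- range(ax)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(ax, breaks, rightmost.closed = TRUE), n_bins)

  out <- lapply(seq_len(n_bins), function(b) {
    sub <- steps[bin == b, ]
    lower <- breaks[b]; upper <- breaks[b + 1]
    if (log_axis) { lower <- 10^lower; upper <- 10^upper }
    n_steps <- nrow(sub)
    if (n_steps < 2) {
      return(tibble::tibble(bin = b, lower = lower, upper = upper,
                            n_steps = n_steps, p_value = NA_real_,
                            significant = NA, testable = FALSE))
    }
    frac <- c(sub$f_within, sub$f_among)
    src <- rep(c(0, 1), each = n_steps)
    delta <- mean(frac[src == 1]) - mean(frac[src == 0])
    resid_ss <- sum((frac[src == 0] - mean(frac[src == 0]))^2) +
      sum((frac[src == 1] - mean(frac[src == 1]))^2)
    if (delta == 0) {
      p <- 1
    } else if (resid_ss == 0) {
      p <- 0
    } else {
      fit <- lm(frac ~ src)
      p <- summary(fit)$coefficients["src", "Pr(>|t|)"]
    }
    tibble::tibble(bin = b, lower = lower, upper = upper, n_steps = n_steps,
                   p_value = p, significant = p <= alpha, testable = TRUE)
  })
  dplyr::bind_rows(out)
}
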