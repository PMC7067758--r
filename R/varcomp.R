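#' Nested variance partitioning of one trait
#'
#' Decomposes trait variation into functional-group, species-within-group
#' and within-species (residual) components with an intercept-only Gaussian
#' model carrying nested random intercepts. Components are estimated by
#' restricted maximum likelihood: the within-species variance is profiled
#' out analytically and the REML criterion is minimised over the two
#' variance ratios (group/within and species/within), constrained to be
#' non-negative, with all boundary configurations evaluated explicitly. The
#' residual variance is reported as the within-species component, and
#' fractions are the components normalised by their total.
#'
#' Traits are treated as log-normal, so values are log-transformed by
#' default before fitting (`scale = "natural"` disables this).
#'
#' @param records Trait records of a *single* trait (columns `value`,
#'   `species`, and `functional_group` unless `hierarchy = "species"`).
#' @param hierarchy `"group_species"` for the full nested hierarchy,
#'   `"species"` to drop the functional-group level.
#' @param scale `"log"` (default) or `"natural"`.
#' @param estimator `"reml"` (default) or `"moments"` for the closed-form
#'   expected-mean-squares estimator (balanced designs only; negative
#'   component estimates are truncated at zero before normalisation).
#' @return An object of class `variance_decomposition`: a list with `trait`,
#'   `components` (named `group`, `species`, `within`), `fractions` (summing
#'   to 1), `n_obs`, `n_species`, `n_groups`, `estimator`, `converged`.
#' @export
fit_variance_components <- function(records,
                                    hierarchy = c("group_species", "species"),
                                    scale = c("log", "natural"),
                                    estimator = c("reml", "moments")) {
  hierarchy <- match.arg(hierarchy)
  scale <- match.arg(scale)
  estimator <- match.arg(estimator)
  trait <- if ("trait" %in% names(records)) {
    tr <- unique(records$trait)
    if (length(tr) > 1) stop_tp("records must contain a single trait")
    tr
  } else NA_character_

  y <- records$value
  if (scale == "log") {
    if (any(y <= 0)) stop_tp("log scale requires strictly positive values")
    y <- log(y)
  }
  species <- as.character(records$species)
  group <- if (hierarchy == "group_species") {
    as.character(records$functional_group)
  } else NULL
  fit <- fit_vc_vectors(y, species, group, estimator)
  fit$trait <- trait
  fit
}

# Core fit on plain vectors; group = NULL drops the group level.
fit_vc_vectors <- function(y, species, group = NULL,
                           estimator = "reml") {
  n_obs <- length(y)
  sp <- factor(species)
  n_species <- nlevels(sp)
  gr <- if (!is.null(group)) factor(group) else NULL
  n_groups <- if (is.null(gr)) NA_integer_ else nlevels(gr)

  degenerate <- function(components) {
    comp <- pmax(components, 0)
    tot <- sum(comp)
    fr <- if (tot > 0) comp / tot else c(group = 0, species = 0, within = 1)
    structure(list(trait = NA_character_, components = comp, fractions = fr,
                   n_obs = n_obs, n_species = n_species, n_groups = n_groups,
                   estimator = estimator, converged = FALSE),
              class = "variance_decomposition")
  }
  if (n_species < 2) {
    v <- if (n_obs >= 2) var(y) else 0
    return(degenerate(c(group = 0, species = 0, within = v)))
  }
  n_s <- as.integer(table(sp))
  if (all(n_s == 1)) {
    # one observation per species: within-species variance unidentifiable;
    # all identifiable variation sits at the species level
    return(degenerate(c(group = 0, species = var(y), within = 0)))
  }
  if (var(y) == 0) {
    return(degenerate(c(group = 0, species = 0, within = 0)))
  }

  if (estimator == "moments") {
    out <- ems_components(y, sp, gr)
  } else {
    out <- reml_nested(y, sp, gr)
  }
  comp <- pmax(out$components, 0)
  tot <- sum(comp)
  fractions <- if (tot > 0) comp / tot else c(group = 0, species = 0, within = 1)
  structure(list(trait = NA_character_, components = comp,
                 fractions = fractions, n_obs = n_obs,
                 n_species = n_species, n_groups = n_groups,
                 estimator = estimator, converged = out$converged),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition",
      if (!is.na(x$trait)) paste0("(", x$trait, ")"), "-",
      x$estimator, if (!x$converged) "[degenerate]", "\n")
  print(round(rbind(component = x$components, fraction = x$fractions), 4))
  invisible(x)
}

# Profiled REML for the intercept-only nested random-intercept model.
# Sufficient statistics are per-species counts, means and within-species
# sums of squares; the within variance is profiled analytically and the
# criterion is minimised over the variance ratios r_g = s2_g/s2_w and
# r_s = s2_s/s2_w (interior search on the log scale plus explicit
# zero-boundary candidates).
reml_nested <- function(y, sp, gr) {
  N <- length(y)
  n_s <- as.numeric(tapply(y, sp, length))
  mean_s <- as.numeric(tapply(y, sp, mean))
  ssw <- sum((y - mean_s[as.integer(sp)])^2)
  two_level <- !is.null(gr) && nlevels(gr) >= 2
  g_of_s <- if (two_level) {
    as.integer(factor(tapply(as.integer(gr), sp, function(i) i[1])))
  } else {
    rep(1L, length(n_s))
  }

  # Zero within-species spread: the residual component is exactly zero and
  # the REML surface is unbounded in the ratios, so partition the species
  # means directly (one-way moment decomposition across groups).
  if (ssw <= 1e-12 * sum((y - mean(y))^2)) {
    if (two_level) {
      gm <- as.numeric(tapply(mean_s, g_of_s, mean))
      s_per_g <- as.numeric(table(g_of_s))
      msw_m <- sum((mean_s - gm[g_of_s])^2) / max(sum(s_per_g - 1), 1)
      msb_m <- if (length(gm) > 1) {
        sum(s_per_g * (gm - mean(mean_s))^2) / (length(gm) - 1)
      } else msw_m
      sg <- max((msb_m - msw_m) / mean(s_per_g), 0)
      comp <- c(group = sg, species = msw_m, within = 0)
    } else {
      comp <- c(group = 0, species = var(mean_s), within = 0)
    }
    return(list(components = comp, converged = TRUE))
  }

  dev <- function(rg, rs) {
    d <- rs + 1 / n_s
    inv_d <- 1 / d
    S11 <- as.numeric(rowsum(inv_d, g_of_s))
    S1y <- as.numeric(rowsum(mean_s * inv_d, g_of_s))
    cg <- 1 + rg * S11
    logdet <- sum(log1p(n_s * rs)) + sum(log(cg))
    q <- ssw + sum(mean_s^2 * inv_d) - rg * sum(S1y^2 / cg)
    u <- sum(S1y / cg)
    w <- sum(S11 / cg)
    Q0 <- q - u^2 / w
    sigw2 <- Q0 / (N - 1)
    if (!is.finite(sigw2) || sigw2 <= 0) return(list(dev = Inf))
    list(dev = (N - 1) * log(sigw2) + logdet + log(w) + (N - 1),
         sigw2 = sigw2)
  }

  # starting ratios from crude moment quantities
  v_tot <- var(y)
  v_within0 <- ssw / max(N - length(n_s), 1)
  start <- max((v_tot - v_within0) / max(v_within0, 1e-8), 0.05)

  best <- list(dev = Inf, rg = 0, rs = 0)
  consider <- function(rg, rs) {
    d <- dev(rg, rs)
    if (d$dev < best$dev) best <<- list(dev = d$dev, rg = rg, rs = rs,
                                        sigw2 = d$sigw2)
  }

  ctrl <- list(rel.tol = 1e-14, x.tol = 1e-12, eval.max = 1000,
               iter.max = 500)
  if (two_level) {
    o <- nlminb(log(c(start, start)),
                function(p) dev(exp(p[1]), exp(p[2]))$dev, control = ctrl)
    consider(exp(o$par[1]), exp(o$par[2]))
    # boundaries: one or both components at zero
    o1 <- optimize(function(ls) dev(0, exp(ls))$dev, c(-30, 10),
                   tol = 1e-12)
    consider(0, exp(o1$minimum))
    o2 <- optimize(function(lg) dev(exp(lg), 0)$dev, c(-30, 10),
                   tol = 1e-12)
    consider(exp(o2$minimum), 0)
    consider(0, 0)
    # coordinate polish around the incumbent
    for (pass in 1:2) {
      if (best$rs > 0) {
        o <- optimize(function(ls) dev(best$rg, exp(ls))$dev,
                      log(best$rs) + c(-2, 2), tol = 1e-13)
        consider(best$rg, exp(o$minimum))
      }
      if (best$rg > 0) {
        o <- optimize(function(lg) dev(exp(lg), best$rs)$dev,
                      log(best$rg) + c(-2, 2), tol = 1e-13)
        consider(exp(o$minimum), best$rs)
      }
    }
  } else {
    # single level: the "group" factor is absent, only r_s is estimated
    o1 <- optimize(function(ls) dev(0, exp(ls))$dev, c(-30, 10), tol = 1e-13)
    consider(0, exp(o1$minimum))
    o <- optimize(function(ls) dev(0, exp(ls))$dev,
                  o1$minimum + c(-1, 1), tol = 1e-14)
    consider(0, exp(o$minimum))
    consider(0, 0)
  }

  sigw2 <- best$sigw2
  comp <- c(group = best$rg * sigw2, species = best$rs * sigw2,
            within = sigw2)
  # ratios indistinguishable from the lower search bound are exact zeros
  comp[1:2][comp[1:2] < 1e-12 * sum(comp)] <- 0
  list(components = comp, converged = TRUE)
}

# Closed-form expected-mean-squares (method-of-moments) estimator for a
# balanced nested design: g groups x s species/group x n obs/species.
ems_components <- function(y, sp, gr) {
  n_s <- as.numeric(table(sp))
  if (length(unique(n_s)) != 1) {
    stop_tp("moments estimator requires a balanced design ",
            "(equal observations per species)")
  }
  n <- n_s[1]
  mean_s <- as.numeric(tapply(y, sp, mean))
  ssw <- sum((y - mean_s[as.integer(sp)])^2)
  if (!is.null(gr) && nlevels(gr) >= 2) {
    g_of_s <- as.integer(factor(tapply(as.integer(gr), sp, function(i) i[1])))
    s_per_g <- as.numeric(table(g_of_s))
    if (length(unique(s_per_g)) != 1) {
      stop_tp("moments estimator requires equal species per group")
    }
    s <- s_per_g[1]
    g <- length(s_per_g)
    mean_g <- as.numeric(tapply(mean_s, g_of_s, mean))
    grand <- mean(mean_s)
    msw <- ssw / (g * s * (n - 1))
    mss <- n * sum((mean_s - mean_g[g_of_s])^2) / (g * (s - 1))
    msg <- s * n * sum((mean_g - grand)^2) / (g - 1)
    comp <- c(group = (msg - mss) / (s * n),
              species = (mss - msw) / n,
              within = msw)
  } else {
    s <- length(mean_s)
    grand <- mean(mean_s)
    msw <- ssw / (s * (n - 1))
    mss <- n * sum((mean_s - grand)^2) / (s - 1)
    comp <- c(group = 0, species = (mss - msw) / n, within = msw)
  }
  list(components = comp, converged = TRUE)
}

#' Site filter for per-site variance partitioning
#'
#' @param min_obs_per_species Minimum observations of the trait a species
#'   must have at the site to be counted (default 4, reading "greater than
#'   three observations per trait per species" literally; set 3 for an
#'   inclusive reading).
#' @param min_species_per_site Minimum number of qualifying species a site
#'   must hold (default 3).
#' @return An object of class `site_filter`.
#' @export
site_filter <- function(min_obs_per_species = 4, min_species_per_site = 3) {
  stopifnot(min_obs_per_species >= 1, min_species_per_site >= 1)
  structure(list(min_obs_per_species = min_obs_per_species,
                 min_species_per_site = min_species_per_site),
            class = "site_filter")
}

#' Per-site variance partitioning with across-site means
#'
#' For every site and trait, retains species with at least
#' `min_obs_per_species` observations of that trait at the site, requires at
#' least `min_species_per_site` such species, fits [fit_variance_components()]
#' on the qualifying records, and summarises fractions as the unweighted
#' mean over qualifying sites per trait plus the grand mean over traits.
#' Traits with no qualifying site are reported absent from the summaries.
#'
#' @param records Trait records (multiple traits allowed).
#' @param filter A [site_filter()].
#' @param scale Analysis scale, `"log"` (default) or `"natural"`.
#' @return A list with `per_site` (tibble: one row per qualifying site x
#'   trait), `by_trait` (across-site mean fractions per trait), and
#'   `grand_mean` (named vector: mean of the by-trait means).
#' @export
partition_by_site <- function(records, filter = site_filter(),
                              scale = "log") {
  stopifnot(inherits(filter, "site_filter"))
  counts <- records %>%
    dplyr::count(.data$site_id, .data$trait, .data$species, name = "n_obs")
  ok <- counts[counts$n_obs >= filter$min_obs_per_species, ]
  site_trait <- ok %>%
    dplyr::count(.data$site_id, .data$trait, name = "n_species") %>%
    dplyr::filter(.data$n_species >= filter$min_species_per_site)

  rows <- vector("list", nrow(site_trait))
  for (i in seq_len(nrow(site_trait))) {
    st <- site_trait[i, ]
    keep_sp <- ok$species[ok$site_id == st$site_id & ok$trait == st$trait]
    sub <- records[records$site_id == st$site_id &
                     records$trait == st$trait &
                     records$species %in% keep_sp, ]
    fit <- fit_variance_components(sub, scale = scale)
    rows[[i]] <- tibble::tibble(
      site_id = st$site_id, trait = st$trait,
      f_group = fit$fractions[["group"]],
      f_species = fit$fractions[["species"]],
      f_within = fit$fractions[["within"]],
      n_obs = fit$n_obs, n_species = fit$n_species,
      converged = fit$converged)
  }
  per_site <- dplyr::bind_rows(rows)
  if (nrow(per_site) == 0) {
    return(list(per_site = per_site,
                by_trait = tibble::tibble(trait = character(),
                                          f_group = numeric(),
                                          f_species = numeric(),
                                          f_within = numeric(),
                                          n_sites = integer()),
                grand_mean = c(f_group = NA_real_, f_species = NA_real_,
                               f_within = NA_real_)))
  }
  by_trait <- per_site %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::summarise(f_group = mean(.data$f_group),
                     f_species = mean(.data$f_species),
                     f_within = mean(.data$f_within),
                     n_sites = dplyr::n(), .groups = "drop")
  grand_mean <- c(f_group = mean(by_trait$f_group),
                  f_species = mean(by_trait$f_species),
                  f_within = mean(by_trait$f_within))
  list(per_site = per_site, by_trait = by_trait, grand_mean = grand_mean)
}

#' Coefficient of variation
#'
#' Sample standard deviation over the mean, on the natural scale.
#'
#' @param values Numeric vector, length at least 2, with non-zero mean.
#' @return A non-negative number.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 0.5
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop_tp("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop_tp("CV undefined for zero mean")
  sd(values) / m
}

#' Per-trait coefficient of variation over all observations
#'
#' @param records Trait records.
#' @return Tibble with columns `trait`, `cv`, `n_obs`.
#' @export
trait_cv <- function(records) {
  records %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::summarise(cv = coefficient_of_variation(.data$value),
                     n_obs = dplyr::n(), .groups = "drop")
}
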