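#' Build a species-by-trait matrix of mean log trait values
#'
#' Aggregates cleaned records to species means of log values (equivalently,
#' the log of the per-species geometric mean), pooling all of a species'
#' records regardless of location. Only species with complete coverage of
#' the selected traits enter the matrix; incomplete species are listed in
#' the `"dropped"` attribute.
#'
#' @param records Cleaned trait records.
#' @param traits Traits forming the columns (default: the six core traits).
#' @return A numeric matrix (species x traits, rownames = species) with
#'   attributes `"dropped"` (species excluded for incomplete coverage) and
#'   `"n_records"` (matrix of per-cell record counts).
#' @export
build_species_matrix <- function(records,
                                 traits = setdiff(TRAIT_LEVELS, "SSD")) {
  records <- records[records$trait %in% traits, ]
  if (any(records$value <= 0)) stop_tp("trait values must be positive")
  agg <- records %>%
    dplyr::group_by(.data$species, .data$trait) %>%
    dplyr::summarise(mean_log = mean(log(.data$value)),
                     n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, id_cols = "species",
                             names_from = "trait",
                             values_from = "mean_log")
  missing_traits <- setdiff(traits, names(wide))
  for (tr in missing_traits) wide[[tr]] <- NA_real_
  M <- as.matrix(wide[, traits, drop = FALSE])
  rownames(M) <- wide$species
  complete <- stats::complete.cases(M)
  dropped <- rownames(M)[!complete]
  M <- M[complete, , drop = FALSE]
  if (nrow(M) < 3) {
    stop_tp("fewer than 3 species with complete trait coverage; ",
            "PCA is not meaningful")
  }
  counts <- tidyr::pivot_wider(agg, id_cols = "species",
                               names_from = "trait", values_from = "n",
                               values_fill = 0L)
  cn <- as.matrix(counts[, intersect(traits, names(counts)), drop = FALSE])
  rownames(cn) <- counts$species
  attr(M, "dropped") <- dropped
  attr(M, "n_records") <- cn[rownames(M), , drop = FALSE]
  M
}

#' Principal component analysis of a species trait matrix
#'
#' Column-centred (and, by default, unit-scaled) singular value
#' decomposition of the species-mean log trait matrix. Axes are ordered by
#' explained variance. Because PCA axis signs are arbitrary, each axis is
#' oriented so that its largest-magnitude loading is positive, which makes
#' results stable across subsets and platforms.
#'
#' @param M Species x trait matrix from [build_species_matrix()].
#' @param standardize Scale columns to unit variance (correlation-matrix
#'   PCA, default `TRUE`; traits have incommensurate units).
#' @return An object of class `trait_pca`: list with `loadings` (trait x
#'   axis), `scores` (species x axis), `explained` (variance fraction per
#'   axis, summing to 1), `contributions` (percent contribution of each
#'   trait to each axis, columns summing to 100), `center`, `scale`,
#'   `standardize`.
#' @export
run_pca <- function(M, standardize = TRUE) {
  if (nrow(M) < 3 || ncol(M) < 2) {
    stop_tp("PCA requires at least 3 species and 2 traits")
  }
  if (standardize) {
    sds <- apply(M, 2, sd)
    zero <- names(sds)[sds == 0]
    if (length(zero)) {
      stop_tp("zero-variance trait column(s): ", paste(zero, collapse = ", "))
    }
  }
  p <- stats::prcomp(M, center = TRUE, scale. = standardize)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  explained <- p$sdev^2 / sum(p$sdev^2)
  contributions <- 100 * sweep(loadings^2, 2, colSums(loadings^2), `/`)
  structure(list(loadings = loadings, scores = scores,
                 explained = explained, contributions = contributions,
                 center = p$center,
                 scale = if (standardize) p$scale else NULL,
                 standardize = standardize),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait-space PCA:", nrow(x$scores), "species,",
      nrow(x$loadings), "traits\n")
  cat("Explained variance:",
      paste(sprintf("%s %.1f%%", colnames(x$loadings),
                    100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Project a species subset within a fitted trait space
#'
#' Returns the scores of a subset of species in the axes of a PCA fitted on
#' the full matrix; subset scores are exactly the corresponding rows of the
#' full score matrix, supporting range comparisons along each axis (e.g.
#' whether a biome's species occupy a constrained part of the global
#' space). Unknown species are listed in the `"skipped"` attribute.
#'
#' @param pca A `trait_pca` fitted on the full species set.
#' @param species Character vector of subset species.
#' @return Score matrix for the known subset species, with attribute
#'   `"skipped"`.
#' @export
subspace_projection <- function(pca, species) {
  stopifnot(inherits(pca, "trait_pca"))
  known <- intersect(species, rownames(pca$scores))
  skipped <- setdiff(species, known)
  out <- pca$scores[known, , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

#' Per-axis score ranges of a subset relative to the full space
#'
#' @param pca A `trait_pca`.
#' @param species Subset species names.
#' @param axes Axes to compare (default first two).
#' @return Tibble with `axis`, `subset_range`, `full_range`, `range_ratio`.
#' @export
axis_range_ratio <- function(pca, species, axes = 1:2) {
  sub <- subspace_projection(pca, species)
  tibble::tibble(
    axis = colnames(pca$scores)[axes],
    subset_range = apply(sub[, axes, drop = FALSE], 2, function(v) diff(range(v))),
    full_range = apply(pca$scores[, axes, drop = FALSE], 2,
                       function(v) diff(range(v)))) %>%
    dplyr::mutate(range_ratio = .data$subset_range / .data$full_range)
}

#' Predict LDMC from stem-specific density
#'
#' Fits a least-squares linear regression of log(LDMC) on log(SSD) to
#' caller-supplied calibration pairs of co-measured values, and predicts
#' LDMC (natural scale) for new SSD values. This supports supplementary
#' comparisons where SSD replaces LDMC; converted values are intended for
#' comparison only, not for the main analysis pipeline.
#'
#' @param ssd SSD values to convert (positive).
#' @param calibration Data frame with positive columns `ssd` and `ldmc` of
#'   co-measured pairs (at least 3).
#' @return Numeric vector of predicted LDMC values, with attribute
#'   `"model"`: list with `slope`, `intercept` (log-log scale) and `r`
#'   (Pearson correlation of the log pairs).
#' @export
ssd_to_ldmc <- function(ssd, calibration) {
  if (!all(c("ssd", "ldmc") %in% names(calibration))) {
    stop_tp("calibration must have columns 'ssd' and 'ldmc'")
  }
  if (nrow(calibration) < 3) stop_tp("need at least 3 calibration pairs")
  if (any(calibration$ssd <= 0) || any(calibration$ldmc <= 0) ||
      any(ssd <= 0)) {
    stop_tp("SSD and LDMC must be positive")
  }
  lx <- log(calibration$ssd)
  ly <- log(calibration$ldmc)
  fit <- lm(ly ~ lx)
  pred <- exp(coef(fit)[1] + coef(fit)[2] * log(ssd))
  attr(pred, "model") <- list(slope = unname(coef(fit)[2]),
                              intercept = unname(coef(fit)[1]),
                              r = stats::cor(lx, ly))
  pred
}
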