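test_that("species matrix holds mean logs and drops incomplete species", {
  recs <- dplyr::bind_rows(
    make_records(c(2, 8), species = "full_sp", trait = "plant_height",
                 id_prefix = "a"),
    make_records(3, species = "full_sp", trait = "LMA", id_prefix = "b"),
    make_records(1, species = "partial_sp", trait = "plant_height",
                 id_prefix = "c"),
    make_records(c(1, 2, 4), species = "sp3", trait = "plant_height",
                 id_prefix = "d"),
    make_records(5, species = "sp3", trait = "LMA", id_prefix = "e"),
    make_records(2, species = "sp4", trait = "plant_height", id_prefix = "f"),
    make_records(7, species = "sp4", trait = "LMA", id_prefix = "g"))
  M <- build_species_matrix(recs, traits = c("plant_height", "LMA"))
  expect_setequal(rownames(M), c("full_sp", "sp3", "sp4"))
  expect_identical(attr(M, "dropped"), "partial_sp")
  # a single-record cell is just the log value
  expect_equal(M["sp4", "plant_height"], log(2))
  # mean of logs equals log of the geometric mean
  expect_equal(M["full_sp", "plant_height"],
               log(sqrt(2 * 8)), tolerance = 1e-12)
  expect_equal(M["sp3", "plant_height"], log(prod(c(1, 2, 4))^(1 / 3)),
               tolerance = 1e-12)
})

test_that("perfectly correlated traits give a single axis", {
  M <- cbind(t1 = log(c(1, 2, 4, 9, 20)), t2 = log(c(2, 4, 8, 18, 40)))
  rownames(M) <- paste0("sp", 1:5)
  p <- run_pca(M)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
})

test_that("PCA invariants hold on generated matrices", {
  db <- generate_database(traitspace_config(seed = 23))
  M <- build_species_matrix(db$records)
  p <- run_pca(M)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(p$contributions)),
               rep(100, ncol(p$contributions)), tolerance = 1e-9)
  # loadings are orthonormal; scores reconstruct the scaled matrix
  expect_equal(crossprod(p$loadings), diag(ncol(M)), tolerance = 1e-9,
               ignore_attr = TRUE)
  Z <- scale(M)
  expect_equal(max(abs(Z - p$scores %*% t(p$loadings))), 0, tolerance = 1e-9)
  # sign convention: the largest-magnitude loading of each axis is positive
  for (k in seq_len(ncol(p$loadings))) {
    v <- p$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("correlation-form PCA ignores per-trait rescaling of raw values", {
  db <- generate_database(traitspace_config(seed = 29))
  recs <- db$records
  p1 <- run_pca(build_species_matrix(recs))
  recs$value[recs$trait == "LMA"] <- recs$value[recs$trait == "LMA"] * 1000
  p2 <- run_pca(build_species_matrix(recs))
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-9)
  expect_equal(p1$explained, p2$explained, tolerance = 1e-9)
})

test_that("zero-variance columns are refused by name", {
  M <- cbind(flat = rep(1, 5), ok = log(1:5))
  rownames(M) <- paste0("sp", 1:5)
  expect_error(run_pca(M), "flat")
})

test_that("the planted two-factor structure dominates the first two axes", {
  db <- generate_database(traitspace_config(seed = 31))
  M <- build_species_matrix(clean_traits(db$records)$records)
  p <- run_pca(M)
  # planted loading directions, rescaled to the correlation space
  L <- db$config$factor_loadings[colnames(M), ] / apply(M, 2, sd)
  Q <- qr.Q(qr(p$loadings[, 1:2]))
  cong <- apply(L, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    sqrt(sum((crossprod(Q, v))^2))
  })
  expect_true(all(cong > 0.95))
  # recovered species scores correlate with the planted factor scores
  sc <- db$truth$factor_scores
  sc <- sc[match(rownames(M), sc$species), ]
  r1 <- max(abs(cor(p$scores[, 1], sc$size_score)),
            abs(cor(p$scores[, 1], sc$econ_score)))
  expect_gt(r1, 0.8)
})

test_that("subset projections reuse the full-space scores", {
  db <- generate_database(traitspace_config(seed = 37))
  M <- build_species_matrix(db$records)
  p <- run_pca(M)
  all_sp <- rownames(M)
  expect_identical(subspace_projection(p, all_sp)[all_sp, ], p$scores)
  one <- subspace_projection(p, all_sp[1])
  expect_identical(nrow(one), 1L)
  skipped <- subspace_projection(p, c(all_sp[1], "not_a_species"))
  expect_identical(attr(skipped, "skipped"), "not_a_species")

  # a subset truncated on the size factor is constrained on the size axis
  sc <- db$truth$factor_scores
  sub <- sc$species[abs(sc$size_score) < 0.5 & sc$species %in% all_sp]
  # identify which PCA axis tracks the size factor
  sc_m <- sc[match(all_sp, sc$species), ]
  size_axis <- which.max(abs(c(cor(p$scores[, 1], sc_m$size_score),
                               cor(p$scores[, 2], sc_m$size_score))))
  other_axis <- setdiff(1:2, size_axis)
  rr <- axis_range_ratio(p, sub, axes = c(size_axis, other_axis))
  # the constrained axis shrinks sharply; the free axis shrinks only by
  # the subsampling of extremes
  expect_lt(rr$range_ratio[1], 0.6)
  expect_gt(rr$range_ratio[2], rr$range_ratio[1] + 0.2)
  expect_gt(rr$range_ratio[2], 0.7)
})

test_that("SSD to LDMC conversion fits and predicts on the log-log line", {
  ssd <- c(0.2, 0.4, 0.8, 1.2)
  ldmc <- exp(0.3 + 0.8 * log(ssd))
  pred <- ssd_to_ldmc(c(0.5, 1.0), data.frame(ssd = ssd, ldmc = ldmc))
  expect_equal(as.numeric(pred), exp(0.3 + 0.8 * log(c(0.5, 1))),
               tolerance = 1e-9)
  m <- attr(pred, "model")
  expect_equal(m$slope, 0.8, tolerance = 1e-9)
  expect_equal(m$r, 1, tolerance = 1e-12)
  # prediction at a calibration point equals the fitted value there
  p2 <- ssd_to_ldmc(ssd[2], data.frame(ssd = ssd, ldmc = ldmc))
  expect_equal(as.numeric(p2), ldmc[2], tolerance = 1e-9)
  expect_error(ssd_to_ldmc(1, data.frame(ssd = c(1, 2), ldmc = c(1, 2))),
               "at least 3")

  # noisy calibration recovers the planted coefficients within a few SEs
  set.seed(8)
  ssd_n <- rlnorm(200, -0.5, 0.4)
  ldmc_n <- exp(0.3 + 0.8 * log(ssd_n) + rnorm(200, 0, 0.1))
  pn <- ssd_to_ldmc(1, data.frame(ssd = ssd_n, ldmc = ldmc_n))
  expect_lt(abs(attr(pn, "model")$slope - 0.8), 0.05)
})
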