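test_that("error risk matches hand arithmetic", {
  # mean of {1,2,3} is 2, sample sd is 1 -> |10 - 2| / 1 = 8
  expect_identical(error_risk(10, c(1, 2, 3, 10)), 8)
  expect_identical(error_risk(10.5, c(1, 2, 3, 10.5)), 8.5)
  expect_identical(error_risk(5, c(5, 5, 5, 5)), 0)
  # zero spread with a deviating value is always removable
  expect_identical(error_risk(9, c(5, 5, 5, 9)), Inf)
  expect_error(error_risk(1, c(1, 2)), "too small")
  # include-x standard deviation variant
  expect_equal(error_risk(10, c(1, 2, 3, 10), sd_excludes_x = FALSE),
               8 / sd(c(1, 2, 3, 10)))
  # vectorised leave-one-out agrees with the scalar definition
  g <- c(1.2, 5.3, 2.2, 9.1, 4.4)
  risks <- traitpart:::loo_risk(g)
  expect_equal(risks, vapply(g, error_risk, numeric(1), group = g))
})

test_that("duplicate ratio counts extra occurrences and dedup respects the cutoff", {
  r0 <- make_records(1:10)
  expect_identical(duplicate_ratio(r0), 0)
  expect_identical(nrow(dedup_within_dataset(r0)), 10L)

  r1 <- make_records(c(1:6, 1:4))          # 4 second copies of 4 originals
  expect_identical(duplicate_ratio(r1), 0.4)
  d1 <- dedup_within_dataset(r1, threshold = 0.3)
  expect_identical(nrow(d1), 6L)
  expect_identical(nrow(attr(d1, "removed")), 4L)

  r2 <- make_records(c(1:7, 1:3))          # ratio exactly 0.30: untouched
  expect_identical(duplicate_ratio(r2), 0.3)
  expect_identical(nrow(dedup_within_dataset(r2, threshold = 0.3)), 10L)

  # duplicates in different datasets do not count as within-dataset copies
  r3 <- dplyr::bind_rows(make_records(c(1, 1, 2), dataset_id = "D1"),
                         make_records(c(1, 1, 2), dataset_id = "D2",
                                      id_prefix = "q"))
  expect_identical(duplicate_ratio(r3[r3$dataset_id == "D1", ]), 1 / 3)
})

test_that("species-level threshold interpolates between the endpoints", {
  expect_identical(species_level_threshold(5), 2.25)
  expect_identical(species_level_threshold(40), 4.0)
  expect_identical(species_level_threshold(20), 3.125)
  expect_identical(species_level_threshold(10), 2.25)
  expect_identical(species_level_threshold(30), 4.0)
  expect_equal(species_level_threshold(c(9, 20, 31)), c(2.25, 3.125, 4.0))
})

test_that("a single extreme record is removed at the global step first", {
  recs <- make_records(c(1, 2, 3, 10.5),
                       species = c("a", "b", "c", "d"),
                       genus = c("ga", "gb", "gc", "gd"))
  out <- clean_traits(recs, dedup = FALSE)
  expect_identical(out$report$record_id, "r4")
  expect_identical(out$report$step, "global")
  expect_equal(out$report$risk, 8.5)
  expect_identical(sort(out$records$record_id), c("r1", "r2", "r3"))
})

test_that("the genus rule screens species present in few datasets", {
  # one genus, three species each in 2 datasets; dataset D9 is 50x off
  set.seed(1)
  base <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_records(exp(rnorm(5, 0, 0.1)),
                 species = paste0("sp", (i + 1) %/% 2),
                 genus = "gen1", dataset_id = paste0("D", i),
                 id_prefix = paste0("r", i, "_"))
  }))
  bad <- make_records(exp(rnorm(5, log(50), 0.1)), species = "sp1",
                      genus = "gen1", dataset_id = "D9", id_prefix = "bad")
  out <- clean_traits(dplyr::bind_rows(base, bad), dedup = FALSE)
  rep_bad <- out$report[out$report$step == "dataset_genus", ]
  expect_true(all(startsWith(rep_bad$record_id, "bad")))
  expect_identical(nrow(rep_bad), 5L)
})

test_that("cleaning a clean synthetic world removes (almost) nothing", {
  db <- generate_database(synthetic_config(outlier_rate = 0,
                                           duplicate_rate = 0, seed = 2))
  out <- clean_traits(db$records)
  expect_false(any(db$truth$record_flags$is_outlier))
  expect_identical(sum(out$report$step == "duplicate"), 0L)
  # no injected artefacts: any removal is a false positive of the screen,
  # which has small but nonzero tail probability
  expect_lt(out$summary$removed_fraction, 0.03)
})

test_that("with infinite thresholds the output equals the input", {
  db <- generate_database(small_scan_config(seed = 4))
  cfg <- cleaning_config(global_risk = Inf, dataset_species_risk = Inf,
                         dataset_genus_risk = Inf,
                         species_risk_min = Inf, species_risk_max = Inf)
  out <- clean_traits(db$records, cfg, dedup = FALSE)
  expect_identical(out$records, db$records)
  expect_identical(nrow(out$report), 0L)
})

test_that("raising a threshold never increases removals at that step", {
  db <- generate_database(synthetic_config(
    n_species = 30, n_sites = 6, n_site_clusters = 2, n_datasets = 25,
    trait_names = c("plant_height", "LMA"), seed = 6))
  n_at <- function(cfg, step) {
    sum(clean_traits(db$records, cfg, dedup = FALSE)$report$step == step)
  }
  expect_gte(n_at(cleaning_config(global_risk = 4), "global"),
             n_at(cleaning_config(global_risk = 8), "global"))
  expect_gte(n_at(cleaning_config(dataset_species_risk = 2), "dataset_species"),
             n_at(cleaning_config(dataset_species_risk = 3), "dataset_species"))
  expect_gte(n_at(cleaning_config(species_risk_min = 1.5, species_risk_max = 2.5),
                  "species"),
             n_at(cleaning_config(), "species"))
})

test_that("the report reconciles with the removals", {
  db <- generate_database(synthetic_config(seed = 8))
  out <- clean_traits(db$records)
  removed <- setdiff(db$records$record_id, out$records$record_id)
  expect_setequal(out$report$record_id, removed)
  expect_identical(anyDuplicated(out$report$record_id), 0L)
  expect_identical(sum(out$summary$per_step$n_removed), length(removed))
  # values of survivors are untouched
  survivors <- dplyr::semi_join(db$records, out$records, by = "record_id")
  expect_identical(survivors$value, out$records$value)
  # every removed record's recorded risk exceeds its step threshold
  risky <- out$report[out$report$step != "duplicate", ]
  expect_true(all(risky$risk > risky$threshold))
})
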