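test_that("haversine distances match the closed forms", {
  expect_identical(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 111.195, tolerance = 1e-3 / 111)
  expect_equal(haversine_km(0, 0, 0, 180), 20015.09, tolerance = 1e-2 / 20015)
  expect_equal(haversine_km(12, 34, -45, 110), haversine_km(-45, 110, 12, 34))
  # random points agree with an independently written formula
  set.seed(4)
  la1 <- runif(20, -80, 80); lo1 <- runif(20, -179, 179)
  la2 <- runif(20, -80, 80); lo2 <- runif(20, -179, 179)
  expect_equal(haversine_km(la1, lo1, la2, lo2),
               haversine_oracle(la1, lo1, la2, lo2), tolerance = 1e-9)
  expect_error(haversine_km(95, 0, 0, 0), "invalid coordinates")
})

scan_fixture <- function() {
  # 3 collinear sites spaced ~111.2 km apart on the equator
  sites <- make_sites(c("S1", "S2", "S3"), latitude = c(0, 0, 0),
                      longitude = c(0, 1, 2))
  recs <- dplyr::bind_rows(lapply(1:3, function(i) {
    r <- make_records(exp(c(0.1, 0.2, 1.1, 1.3, 2.0, 2.2)) * i,
                      species = rep(c("a", "b", "c"), each = 2),
                      functional_group = rep(c("f1", "f1", "f2"), each = 2),
                      site_id = paste0("S", i), id_prefix = paste0("s", i, "_"))
    r
  }))
  list(records = recs, sites = sites)
}

test_that("the scan adds sites in distance order from the start", {
  fx <- scan_fixture()
  st <- scan_from_site(fx$records, fx$sites, "S1")
  d <- haversine_km(0, 0, 0, 1)
  expect_equal(unique(st$scale_km), c(0, d, 2 * d), tolerance = 1e-9)
  expect_identical(unique(st$step_index), c(0L, 1L, 2L))
  # starting from the middle site ties are impossible; from an end the
  # order must match a brute-force sort
  ord <- order(haversine_km(0, 0, fx$sites$latitude, fx$sites$longitude))
  expect_identical(fx$sites$site_id[ord], c("S1", "S2", "S3"))
})

test_that("an ineligible start site is rejected", {
  fx <- scan_fixture()
  expect_error(scan_from_site(fx$records, fx$sites, "S9"), "not eligible")
  # raise the bar so no site qualifies
  expect_error(scan_from_site(fx$records, fx$sites, "S1",
                              min_species = 10), "not eligible")
})

test_that("scan_all_sites enumerates every start and is deterministic", {
  fx <- scan_fixture()
  st <- scan_all_sites(fx$records, fx$sites)
  n_elig <- length(eligible_sites(fx$records))
  expect_identical(n_elig, 3L)
  # per trait: sum over starts of number of eligible sites
  expect_identical(nrow(st), n_elig * n_elig * 1L)
  st2 <- scan_all_sites(fx$records, fx$sites)
  expect_identical(st, st2)
  # invariant to input row order
  set.seed(1)
  st3 <- scan_all_sites(fx$records[sample(nrow(fx$records)), ], fx$sites)
  expect_equal(st, st3, tolerance = 1e-12)
})

test_that("scale and richness are nondecreasing along every scan", {
  db <- generate_database(small_scan_config(seed = 19))
  st <- scan_all_sites(db$records, db$sites)
  for (s in split(st, st$start_site_id)) {
    s <- s[order(s$step_index), ]
    expect_true(all(diff(s$scale_km[s$trait == s$trait[1]]) >= 0))
    expect_true(all(diff(s$richness[s$trait == s$trait[1]]) >= 0))
  }
  # at the final step the measured pool is the whole species list
  final <- st[st$step_index == max(st$step_index), ]
  expect_identical(unique(final$richness),
                   dplyr::n_distinct(db$records$species))
  # within + among fractions sum to one at every step
  expect_equal(st$f_within + st$f_among, rep(1, nrow(st)), tolerance = 1e-9)
})

test_that("binned summaries match a brute-force percentile oracle", {
  set.seed(7)
  steps <- tibble::tibble(scale_km = runif(1000, 0, 50),
                          richness = sample(1:30, 1000, TRUE),
                          f_within = runif(1000),
                          f_among = runif(1000))
  out <- bin_and_interval(steps, "scale_km", width = 5)
  # oracle: sort-and-interpolate percentile (type-7 definition), per bin
  oracle_q <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p
    lo <- floor(h) + 1
    v[lo] + (h - floor(h)) * (v[min(lo + 1, length(v))] - v[lo])
  }
  for (b in unique(out$bin)) {
    v <- steps$f_within[floor(steps$scale_km / 5) == b]
    row <- out[out$bin == b & out$source == "within", ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$lower95, oracle_q(v, 0.025))
    expect_equal(row$upper95, oracle_q(v, 0.975))
    expect_true(row$lower95 <= row$mean && row$mean <= row$upper95)
  }
})

test_that("degenerate bins collapse to their single value", {
  steps <- tibble::tibble(scale_km = c(1, 2, 3), richness = 1:3,
                          f_within = c(0.4, 0.4, 0.4),
                          f_among = c(0.6, 0.6, 0.6))
  out <- bin_and_interval(steps, "scale_km", width = 10)
  expect_identical(nrow(out), 2L)
  w <- out[out$source == "within", ]
  expect_identical(c(w$lower95, w$mean, w$upper95), rep(0.4, 3))
})

test_that("bin significance testing matches a two-sample t oracle", {
  set.seed(11)
  steps <- tibble::tibble(scale_km = runif(60, 1, 100),
                          richness = sample(5:20, 60, TRUE),
                          f_within = c(rnorm(30, 0.9, 0.02),
                                       rnorm(30, 0.5, 0.02)),
                          f_among = c(rnorm(30, 0.1, 0.02),
                                      rnorm(30, 0.5, 0.02)))
  out <- test_bin_significance(steps, "scale_km", n_bins = 4)
  breaks <- seq(log10(min(steps$scale_km)), log10(max(steps$scale_km)),
                length.out = 5)
  for (b in out$bin[out$testable]) {
    sel <- pmin(findInterval(log10(steps$scale_km), breaks,
                             rightmost.closed = TRUE), 4) == b
    tt <- t.test(steps$f_among[sel], steps$f_within[sel], var.equal = TRUE)
    expect_equal(out$p_value[out$bin == b], tt$p.value, tolerance = 1e-9)
  }
  # label swap changes the sign of the difference, not the p-value
  swapped <- steps
  swapped$f_within <- steps$f_among
  swapped$f_among <- steps$f_within
  out2 <- test_bin_significance(swapped, "scale_km", n_bins = 4)
  expect_equal(out$p_value, out2$p_value, tolerance = 1e-12)
})

test_that("identical sources in a bin are never significant", {
  steps <- tibble::tibble(scale_km = runif(20, 1, 10),
                          richness = 1:20,
                          f_within = rep(0.5, 20), f_among = rep(0.5, 20))
  out <- test_bin_significance(steps, "scale_km", n_bins = 2)
  expect_true(all(out$p_value[out$testable] == 1))
  expect_false(any(out$significant[out$testable]))
})
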