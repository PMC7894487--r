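test_that("stem diversification estimator matches its closed form", {
  expect_identical(stem_diversification_rate(1, 10, 0.5), 0)
  expect_equal(stem_diversification_rate(100, 50, 0), log(100) / 50)
  # independent evaluation through log1p((n-1)(1-eps)) == log(n(1-eps)+eps)
  expect_equal(stem_diversification_rate(1000, 100, 0.9),
               log1p(999 * 0.1) / 100, tolerance = 1e-14)
  expect_equal(stem_diversification_rate(1000, 100, 0.9), 0.0461413,
               tolerance = 1e-5)
})

test_that("estimator rejects out-of-domain arguments", {
  expect_error(stem_diversification_rate(100, 0, 0.9), "stem age")
  expect_error(stem_diversification_rate(100, -5, 0.9), "stem age")
  expect_error(stem_diversification_rate(0, 10, 0.9), "richness")
  expect_error(stem_diversification_rate(100, 10, 1), "epsilon")
  expect_error(stem_diversification_rate(100, 10, -0.1), "epsilon")
  expect_error(stem_diversification_rate(100.5, 10, 0.5), "integer")
  expect_error(stem_diversification_rate(NA, 10, 0.5), "finite")
})

test_that("estimator is increasing in n, decreasing in t, and eps-ordered", {
  n <- c(2, 5, 20, 100, 1000, 5000)
  expect_true(all(diff(stem_diversification_rate(n, 50, 0.9)) > 0))
  t <- c(5, 20, 50, 100, 200)
  expect_true(all(diff(stem_diversification_rate(100, t, 0.9)) < 0))
  for (nn in c(1, 2, 10, 1000)) {
    eps_grid <- seq(0, 0.99, length.out = 50)
    r <- stem_diversification_rate(nn, 50, eps_grid)
    expect_true(all(diff(r) <= 1e-15))  # continuous, non-increasing in eps
    expect_gte(stem_diversification_rate(nn, 50, 0),
               stem_diversification_rate(nn, 50, 0.9))
  }
})

test_that("high-richness families have close eps=0 and eps=0.9 rates", {
  set.seed(1)
  n <- round(runif(100, 1000, 20000))
  t <- runif(100, 30, 150)
  r0 <- stem_diversification_rate(n, t, 0)
  r9 <- stem_diversification_rate(n, t, 0.9)
  expect_true(all(abs(r0 - r9) / r0 < 0.35))
})

test_that("species range sizes sum region areas; zonal parts sum to total", {
  regions <- data.frame(region_id = c("R1", "R2", "R3"),
                        area_km2 = c(100, 250.5, 40),
                        tropical_km2 = c(60, 0, 40),
                        temperate_km2 = c(40, 250.5, 0))
  validate_region_table(regions)
  expect_equal(species_range_size("R1", regions), 100)
  expect_equal(species_range_size(c("R1", "R2"), regions), 350.5)
  expect_equal(species_range_size(character(0), regions), 0)
  expect_error(species_range_size("R9", regions), "R9")

  expect_equal(species_zonal_range("R1", regions),
               c(tropical_km2 = 60, temperate_km2 = 40))
  expect_equal(species_zonal_range(c("R1", "R2"), regions),
               c(tropical_km2 = 60, temperate_km2 = 290.5))

  set.seed(5)
  for (i in 1:20) {
    ids <- sample(regions$region_id, sample(1:3, 1))
    z <- species_zonal_range(ids, regions)
    expect_equal(unname(sum(z)), species_range_size(ids, regions),
                 tolerance = 1e-12)
  }
})

test_that("region table invariants are enforced", {
  bad <- data.frame(region_id = "R1", area_km2 = 100,
                    tropical_km2 = 70, temperate_km2 = 40)
  expect_error(validate_region_table(bad), "tropical")
  expect_error(validate_region_table(
    data.frame(region_id = c("R1", "R1"), area_km2 = 1,
               tropical_km2 = 0.5, temperate_km2 = 0.5)), "duplicate")
})

test_that("mean family range agrees with an independent summation oracle", {
  fx <- make_filter_fixture()
  expect_equal(mean_family_range("FamA", fx$species, fx$occurrences, fx$regions), 100)
  # brute-force oracle on a simulated 50-species family
  set.seed(77)
  b <- small_bundle(seed = 20, n_families = 10, n_regions = 20)
  fam <- b$family_data$family[which.max(b$family_data$n_species)]
  nat <- b$occurrences[b$occurrences$status == "native", ]
  ids <- b$species$species_id[b$species$family == fam]
  oracle <- mean(vapply(ids, function(id) {
    rs <- unique(nat$region_id[nat$species_id == id])
    sum(b$regions$area_km2[match(rs, b$regions$region_id)])
  }, numeric(1)))
  expect_equal(mean_family_range(fam, b$species, b$occurrences, b$regions),
               oracle, tolerance = 1e-9)
  # no distribution data -> NA
  expect_true(is.na(mean_family_range("FamD", fx$species, fx$occurrences, fx$regions)))
})

test_that("coverage subsets partition the family's species", {
  fx <- make_filter_fixture()
  all_sp <- family_range_sizes("FamA", fx$species, fx$occurrences, fx$regions)
  glob <- family_range_sizes("FamA", fx$species, fx$occurrences, fx$regions,
                             subset = "global_coverage")
  part <- family_range_sizes("FamA", fx$species, fx$occurrences, fx$regions,
                             subset = "partial_coverage")
  expect_setequal(names(all_sp), c(names(glob), names(part)))
  expect_equal(length(all_sp), length(glob) + length(part))
  # independent filter oracle for the subset means
  flags <- fx$species$coverage_flag[match(names(all_sp), fx$species$species_id)]
  expect_equal(mean(glob), mean(all_sp[flags == "complete"]))
  expect_equal(mean(part), mean(all_sp[flags == "partial"]))
  expect_error(
    family_range_sizes("FamA", fx$species, fx$occurrences, fx$regions,
                       subset = "bogus"), "arg")
})

test_that("naturalization success index: arithmetic, linearity, errors", {
  expect_equal(naturalization_success(0, 50, 0), 0)
  expect_equal(naturalization_success(5, 50, 12), 1.2)
  expect_equal(naturalization_success(5, 50, 24), 2 * naturalization_success(5, 50, 12))
  expect_error(naturalization_success(51, 50, 60), "inconsisten")
  expect_error(naturalization_success(5, 50, 3), "inconsisten")
  expect_error(naturalization_success(0, 0, 0), "n_total")
})

test_that("horticultural use proportion", {
  expect_equal(horticultural_use(0, 100), 0)
  expect_equal(horticultural_use(100, 100), 1)
  expect_equal(horticultural_use(25, 200), 0.125)
  expect_error(horticultural_use(201, 200), "inconsisten")
})

test_that("family filter retains exactly the designed families with reasons", {
  fx <- make_filter_fixture()
  res <- suppressMessages(build_family_dataset(
    fx$species, fx$occurrences, fx$regions, fx$tree, ages = fx$ages))
  expect_equal(res$data$family, "FamA")
  reasons <- setNames(res$excluded$reason, res$excluded$family)
  expect_equal(reasons[["FamB"]], "min_richness")
  expect_equal(reasons[["FamC"]], "no_phylogeny")
  expect_equal(reasons[["FamD"]], "no_range_data")
  expect_equal(reasons[["FamE"]], "min_richness")   # only 45 accepted species
  expect_equal(reasons[["FamF"]], "no_stem_age")

  row <- res$data[1, ]
  expect_equal(row$n_species, 50)
  expect_equal(row$n_naturalized, 5)
  expect_equal(row$naturalized_region_records, 12)
  expect_equal(row$nat_success, 1.2)
  expect_equal(row$hort_prop, 0.2)
  expect_equal(row$mean_range_km2, 100)
  expect_equal(row$mean_tropical_km2, 60)
  expect_equal(row$mean_temperate_km2, 40)
  expect_equal(row$div_rate, log(50 * 0.1 + 0.9) / 50)
  expect_equal(row$div_rate_eps0, log(50) / 50)
  # zonal means sum to the total mean
  expect_equal(row$mean_tropical_km2 + row$mean_temperate_km2,
               row$mean_range_km2, tolerance = 1e-9)
})

test_that("min_richness is configurable and empty results error", {
  fx <- make_filter_fixture()
  res <- suppressMessages(build_family_dataset(
    fx$species, fx$occurrences, fx$regions, fx$tree, ages = fx$ages,
    min_richness = 40))
  expect_setequal(res$data$family, c("FamA", "FamE"))
  expect_error(
    suppressMessages(build_family_dataset(
      fx$species, fx$occurrences, fx$regions, fx$tree, ages = fx$ages,
      min_richness = 1000)),
    "no family")
})
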