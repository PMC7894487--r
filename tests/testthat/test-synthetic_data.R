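test_that("simulate_tree: determinism, tip count, Yule 2-tip stem ages", {
  t1 <- simulate_tree(20, seed = 5)
  t2 <- simulate_tree(20, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_false(identical(write_newick(t1), write_newick(simulate_tree(20, seed = 6))))
  expect_equal(length(t1$tip.label), 20)
  expect_error(simulate_tree(10, birth = 0.05, death = 0.05), "birth")

  y2 <- simulate_tree(2, birth = 0.1, death = 0, seed = 3)
  a <- stem_ages(y2)
  expect_equal(a[[1]], a[[2]], tolerance = 1e-12)  # both date to the single split
})

test_that("pure-birth waiting times follow the Yule law E[dur_k] = 1/(k b)", {
  # while k lineages exist a birth process waits Exp(k b); check the
  # simulator's inter-speciation durations against that closed form (3 SE)
  set.seed(52)
  b <- 0.2; n <- 6; reps <- 600
  durs <- matrix(NA_real_, reps, n - 1)
  for (r in 1:reps) {
    tr <- simulate_tree(n, birth = b, death = 0, seed = 5000 + r)
    bt <- sort(ape::branching.times(tr), decreasing = TRUE)
    durs[r, ] <- c(-diff(bt), bt[n - 1])   # durations with k = 2, ..., n lineages
  }
  for (k in 2:n) {
    est <- mean(durs[, k - 1])
    se <- sd(durs[, k - 1]) / sqrt(reps)
    expect_lt(abs(est - 1 / (k * b)), 3 * se)
  }
})

test_that("simulate_regions: construction invariants and log-normal mean", {
  r <- simulate_regions(1000, area_meanlog = 10, area_sdlog = 1, seed = 7)
  expect_equal(nrow(r), 1000)
  expect_true(all(r$area_km2 > 0))
  expect_equal(r$tropical_km2 + r$temperate_km2, r$area_km2, tolerance = 1e-9)
  expect_silent(validate_region_table(r))
  # closed-form log-normal mean exp(mu + sigma^2/2), 3-SE band
  m_true <- exp(10 + 0.5)
  sd_true <- sqrt((exp(1) - 1) * exp(2 * 10 + 1))
  expect_lt(abs(mean(r$area_km2) - m_true), 3 * sd_true / sqrt(1000))

  all_temp <- simulate_regions(50, trop_shape1 = 0, seed = 8)
  expect_true(all(all_temp$tropical_km2 == 0))
  expect_equal(all_temp$temperate_km2, all_temp$area_km2)
})

test_that("brownian_effects: zero variance, star independence, covariance", {
  tr <- simulate_tree(10, seed = 9)
  expect_equal(unname(brownian_effects(tr, 0, seed = 1)), rep(0, 10))

  star <- read_newick(paste0("(", paste0("T", 1:6, ":1", collapse = ","), ");"))
  draws <- t(vapply(1:2000, function(i) brownian_effects(star, 1, seed = i),
                    numeric(6)))
  C <- cov(draws)
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)  # i.i.d. on a star tree
  expect_equal(unname(diag(C)), rep(1, 6), tolerance = 0.15)

  # empirical covariance ~ sigma2 * A on a structured tree
  A <- phylo_covariance(tr)
  dr <- t(vapply(1:2000, function(i) brownian_effects(tr, 2, seed = 10000 + i),
                 numeric(10)))
  expect_lt(norm(cov(dr) - 2 * A[tr$tip.label, tr$tip.label], "F") /
              norm(2 * A, "F"), 0.10)
})

test_that("component seeds are deterministic, distinct, and in int range", {
  s1 <- component_seed(42, "tree")
  expect_identical(s1, component_seed(42, "tree"))
  expect_false(s1 == component_seed(42, "regions"))
  expect_false(s1 == component_seed(43, "tree"))
  for (m in c(1, 1000, 2^30)) {
    s <- component_seed(m, "species")
    expect_true(s >= 0 && s < 2^31)
    expect_true(is.integer(s))
  }
})

test_that("generated tables satisfy all type invariants", {
  b <- small_bundle(seed = 61)
  expect_silent(validate_region_table(b$regions))
  expect_silent(validate_phylogeny(b$tree))
  expect_false(anyDuplicated(b$species$species_id) > 0)
  expect_true(all(b$occurrences$region_id %in% b$regions$region_id))
  expect_true(all(b$occurrences$species_id %in% b$species$species_id))
  fd <- b$family_data
  expect_true(all(fd$n_naturalized <= fd$n_species))
  expect_true(all(fd$n_naturalized >= 1))
  expect_true(all(fd$naturalized_region_records >= fd$n_naturalized))
  expect_true(all(fd$hort_prop >= 0 & fd$hort_prop <= 1))
  expect_true(all(fd$nat_success > 0))
  expect_true(all((fd$nat_success == 0) == (fd$n_naturalized == 0)))
  # some families designed to fail the 50-species filter
  expect_gt(length(setdiff(b$tree$tip.label, fd$family)), 0)
  # the eps = 0 estimator recovers the generator's true rates exactly
  expect_equal(fd$div_rate_eps0,
               unname(b$truth$r_true[fd$family]), tolerance = 1e-12)
})

test_that("noise-free construction reproduces the linear predictor", {
  cfg <- simulation_config(n_families = 40, n_regions = 50, sigma2_p = 0,
                           sigma2_e = 0, max_richness = 3000, seed = 71)
  b <- suppressMessages(simulate_study(cfg))
  s_target <- b$truth$latent
  s_achieved <- sqrt(b$family_data$nat_success)
  # integer rounding of (n_nat, records) is the only discrepancy
  expect_lt(max(abs(s_achieved - s_target)), 0.2)
  expect_lt(mean(abs(s_achieved - s_target)), 0.05)
  # and the latent equals mu0 + X beta exactly when both variances vanish
  tmap <- default_transforms()
  X <- vapply(names(cfg$beta), function(col)
    standardize(transform_values(b$family_data[[col]], tmap[[col]])),
    numeric(nrow(b$family_data)))
  expect_equal(unname(s_target), cfg$mu0 + drop(X %*% cfg$beta), tolerance = 1e-9)
})

test_that("null generator: beta = 0, no phylo signal -> no association", {
  cfg <- simulation_config(n_families = 80, n_regions = 50, sigma2_p = 0,
                           beta = c(div_rate = 0, mean_range_km2 = 0, hort_prop = 0),
                           max_richness = 2000, seed = 72)
  b <- suppressMessages(simulate_study(cfg))
  d <- build_design(b$family_data, model_spec("model1"))
  n <- nrow(d$X)
  for (j in 2:4) {
    expect_lt(abs(cor(d$y, d$X[, j])), 3 / sqrt(n))
  }
})

test_that("pipeline recomputation equals the generator's family dataset", {
  b <- small_bundle(seed = 62)
  built <- suppressMessages(build_family_dataset(
    b$species, b$occurrences, b$regions, b$tree))
  g <- b$family_data[order(b$family_data$family), ]
  p <- built$data[order(built$data$family), ]
  expect_identical(p$family, g$family)
  expect_identical(p$n_species, g$n_species)
  expect_identical(p$n_naturalized, g$n_naturalized)
  expect_identical(p$naturalized_region_records, g$naturalized_region_records)
  expect_equal(p$nat_success, g$nat_success, tolerance = 1e-12)
  expect_equal(p$mean_range_km2, g$mean_range_km2, tolerance = 1e-9)
  expect_equal(p$mean_tropical_km2, g$mean_tropical_km2, tolerance = 1e-9)
  expect_equal(p$mean_temperate_km2, g$mean_temperate_km2, tolerance = 1e-9)
  expect_equal(p$div_rate, g$div_rate, tolerance = 1e-12)
  expect_equal(p$hort_prop, g$hort_prop, tolerance = 1e-12)
})

test_that("bundle write/read round-trips through plain-text files", {
  b <- small_bundle(seed = 63, n_families = 10, n_regions = 15)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "regions.csv",
                                               "species.csv", "occurrences.csv",
                                               "truth.json")))))
  back <- read_bundle(dir)
  lab <- sort(b$tree$tip.label)
  expect_equal(tip_distances(back$tree)[lab, lab], tip_distances(b$tree)[lab, lab],
               tolerance = 1e-6)
  expect_equal(back$regions$area_km2, b$regions$area_km2, tolerance = 1e-9)
  expect_identical(back$species$species_id, b$species$species_id)
  expect_equal(nrow(back$occurrences), nrow(b$occurrences))
  expect_equal(unlist(back$truth$beta), b$truth$beta, tolerance = 1e-12)
})
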