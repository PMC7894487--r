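#' Derive a component seed from the master seed
#'
#' Deterministic splitting rule so each simulation component (tree, regions,
#' species, ...) is independently reproducible: the component name is hashed
#' (polynomial rolling hash of its UTF-8 bytes) and combined with the master
#' seed modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param component component name.
#' @return integer seed.
#' @export
component_seed <- function(master, component) {
  bytes <- utf8ToInt(component)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' 200 candidate families (so that, after the richness filter, on the order
#' of 170 remain, matching the scale of the real 168-family analysis),
#' birth-death family tree in Myr, log-normal region areas, Beta-distributed
#' tropical fractions, and true regression coefficients
#' beta = (0.5, 0.4, 0.38) on the standardized (diversification rate, mean
#' range, horticultural use) predictors with sigma2_p = sigma2_e = 1 --
#' effect magnitudes of the size the family-level analysis reports.
#'
#' @param n_families candidate families (tree tips).
#' @param birth,death family birth-death rates per Myr.
#' @param n_regions number of regions.
#' @param area_meanlog,area_sdlog log-normal region-area parameters (km^2).
#' @param trop_shape1,trop_shape2 Beta parameters of the tropical fraction.
#' @param richness_meanlog,richness_sdlog log-normal family richness
#'   parameters; the true net rate of a family is then log(richness)/stem
#'   age, so the epsilon = 0 stem estimator recovers it exactly.
#' @param max_richness richness cap.
#' @param small_family_frac fraction of families forced below the
#'   50-species inclusion filter.
#' @param beta named true coefficient vector on the standardized predictor
#'   scale.
#' @param mu0 latent intercept on the sqrt response scale (keeps the latent
#'   score positive).
#' @param sigma2_p,sigma2_e phylogenetic and residual variances.
#' @param hort_shape1,hort_shape2 Beta parameters of family horticulture
#'   propensity.
#' @param epsilon relative extinction used for the generator's own
#'   diversification-rate column.
#' @param min_richness inclusion filter (matches the pipeline default).
#' @param n_orders number of taxonomic orders.
#' @param seed master seed.
#' @return a \code{natdiv_sim_config} list.
#' @export
simulation_config <- function(n_families = 200, birth = 0.08, death = 0.04,
                              n_regions = 150,
                              area_meanlog = 11, area_sdlog = 1.3,
                              trop_shape1 = 0.8, trop_shape2 = 0.8,
                              richness_meanlog = log(250), richness_sdlog = 1.2,
                              max_richness = 5000,
                              small_family_frac = 0.1,
                              beta = c(div_rate = 0.5, mean_range_km2 = 0.4,
                                       hort_prop = 0.38),
                              mu0 = 4, sigma2_p = 1, sigma2_e = 1,
                              hort_shape1 = 1.2, hort_shape2 = 2.8,
                              epsilon = 0.9, min_richness = 50,
                              n_orders = 30, seed = 1) {
  stopifnot(birth > death, death >= 0, n_families >= 4, n_regions >= 2,
            sigma2_p >= 0, sigma2_e >= 0,
            small_family_frac >= 0, small_family_frac < 1)
  structure(as.list(environment()), class = "natdiv_sim_config")
}

#' Simulate a dated family tree
#'
#' Birth-death tree conditioned on \code{n_tips} extant survivors
#' (reconstructed tree; branch lengths in Myr), with tips labelled
#' \code{Fam001, Fam002, ...}.
#'
#' @param n_tips number of extant tips.
#' @param birth,death rates per Myr (birth > death >= 0).
#' @param seed integer seed.
#' @return a \code{phylo} object; stem ages via \code{\link{stem_ages}}.
#' @export
simulate_tree <- function(n_tips, birth = 0.08, death = 0.04, seed = 1) {
  stopifnot(birth > death, death >= 0, n_tips >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = death, fossils = FALSE)
  tree$tip.label <- sprintf("Fam%03d", seq_len(n_tips))
  validate_phylogeny(tree)
  tree
}

#' Simulate a region table
#'
#' Region areas are log-normal; each region's tropical share is an
#' independent Beta draw, the temperate area the remainder, so the zonal
#' components sum exactly to the total.
#'
#' @param n_regions number of regions (>= 2).
#' @param area_meanlog,area_sdlog log-normal parameters of area (km^2).
#' @param trop_shape1,trop_shape2 Beta parameters of the tropical fraction.
#' @param seed integer seed.
#' @return a valid region table.
#' @export
simulate_regions <- function(n_regions, area_meanlog = 11, area_sdlog = 1.3,
                             trop_shape1 = 0.8, trop_shape2 = 0.8, seed = 1) {
  stopifnot(n_regions >= 2)
  set.seed(seed)
  area <- stats::rlnorm(n_regions, area_meanlog, area_sdlog)
  frac <- if (trop_shape1 == 0) {
    rep(0, n_regions)        # fully temperate world
  } else if (trop_shape2 == 0) {
    rep(1, n_regions)        # fully tropical world
  } else {
    stats::rbeta(n_regions, trop_shape1, trop_shape2)
  }
  regions <- data.frame(
    region_id = sprintf("R%04d", seq_len(n_regions)),
    area_km2 = area,
    tropical_km2 = area * frac,
    temperate_km2 = area * (1 - frac),
    stringsAsFactors = FALSE
  )
  validate_region_table(regions)
  regions
}

#' Brownian tip effects on a tree
#'
#' One draw from Normal(0, sigma2 * A), A the phylogenetic correlation of
#' the tree -- the phylogenetic random effect of the mixed model.
#'
#' @param tree a \code{phylo} object.
#' @param sigma2 variance (>= 0).
#' @param seed integer seed.
#' @return named tip-effect vector.
#' @export
brownian_effects <- function(tree, sigma2, seed = 1) {
  stopifnot(sigma2 >= 0)
  tips <- tree$tip.label
  if (sigma2 == 0) return(stats::setNames(rep(0, length(tips)), tips))
  A <- phylo_covariance(tree)
  set.seed(seed)
  z <- stats::rnorm(length(tips))
  eig <- eigen(A, symmetric = TRUE)
  L <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  stats::setNames(drop(L %*% z) * sqrt(sigma2), tips)
}

#' Simulate the species-level input tables with known ground truth
#'
#' Generates the full species checklist and occurrence tables from the tree
#' and region table such that the family-level pipeline recomputes exactly
#' the generator's own family dataset, and the naturalization response
#' carries a known linear signal: for families passing the richness filter
#' the latent score on the sqrt scale is
#' \deqn{s_f = \mu_0 + x_f' \beta + u_f + e_f}
#' with standardized predictors x, Brownian tip effects u ~ N(0, sigma2_p A)
#' and e ~ N(0, sigma2_e I); naturalized counts are then constructed so that
#' sqrt(naturalization success) reproduces s_f up to integer rounding
#' (relative error O(1/sqrt(n_nat * records))).
#'
#' @param tree family tree from \code{\link{simulate_tree}}.
#' @param regions region table from \code{\link{simulate_regions}}.
#' @param config a \code{\link{simulation_config}}.
#' @param seed integer seed.
#' @return list: \code{species}, \code{occurrences} (long native +
#'   naturalized records), \code{family_data} (the generator's family
#'   dataset for filter-passing families), \code{truth} (beta, mu0,
#'   variances, u, latent scores, achieved sqrt-scale response).
#' @export
simulate_species_tables <- function(tree, regions, config, seed = 1) {
  set.seed(seed)
  fams <- tree$tip.label
  nf <- length(fams)
  ages <- stem_ages(tree)

  # log-normal family richness; the true net rate is tied to the stem
  # estimator's own model: r_true = log(n)/t, so the eps = 0 estimator
  # recovers it exactly on the generated families
  richness <- round(pmin(stats::rlnorm(nf, config$richness_meanlog,
                                       config$richness_sdlog),
                         config$max_richness))
  richness <- as.integer(pmax(richness, 1L))
  n_small <- round(config$small_family_frac * nf)
  if (n_small > 0) {
    small_idx <- sample(nf, n_small)
    richness[small_idx] <- sample(seq(5, config$min_richness - 1), n_small,
                                  replace = TRUE)
  }
  r_true <- ifelse(richness > 1, log(richness) / ages[fams], 0)

  # taxonomic orders: patristic clustering of the family tree
  n_ord <- min(config$n_orders, nf)
  cl <- stats::cutree(stats::hclust(stats::as.dist(tip_distances(tree)), "average"),
                      k = n_ord)
  orders <- sprintf("Order%02d", cl[fams])

  # family-level biogeographic propensities
  affinity <- stats::runif(nf)                       # tropical affinity
  trop_frac <- regions$tropical_km2 / regions$area_km2
  hort_prop_true <- stats::rbeta(nf, config$hort_shape1, config$hort_shape2)

  species_rows <- vector("list", nf)
  native_rows <- vector("list", nf)
  pool_size <- min(nrow(regions), 30)
  for (f in seq_len(nf)) {
    n_sp <- richness[f]
    ids <- sprintf("%s_sp%04d", fams[f], seq_len(n_sp))
    w <- affinity[f] * trop_frac + (1 - affinity[f]) * (1 - trop_frac) + 0.01
    pool <- sample(nrow(regions), pool_size, prob = w)
    occ_n <- 1 + stats::rpois(n_sp, 2)
    occ_n <- pmin(occ_n, pool_size)
    native_rows[[f]] <- data.frame(
      species_id = rep(ids, occ_n),
      region_id = regions$region_id[unlist(lapply(occ_n, function(k)
        sample(pool, k)))],
      status = "native",
      stringsAsFactors = FALSE
    )
    species_rows[[f]] <- data.frame(
      species_id = ids,
      family = fams[f],
      order = orders[f],
      accepted = TRUE,
      horticultural = stats::runif(n_sp) < hort_prop_true[f],
      coverage_flag = ifelse(stats::runif(n_sp) < 0.8, "complete", "partial"),
      stringsAsFactors = FALSE
    )
  }
  species <- do.call(rbind, species_rows)
  native <- do.call(rbind, native_rows)

  # generator-side family metrics for filter-passing families
  passing <- fams[richness >= config$min_richness]
  metrics <- lapply(passing, function(fam) {
    tot <- family_range_sizes(fam, species, native, regions)
    trp <- family_range_sizes(fam, species, native, regions, zone = "tropical")
    tmp <- family_range_sizes(fam, species, native, regions, zone = "temperate")
    n_sp <- richness[match(fam, fams)]
    data.frame(family = fam, order = orders[match(fam, fams)],
               n_species = n_sp,
               stem_age = unname(ages[fam]),
               div_rate = stem_diversification_rate(n_sp, ages[fam], config$epsilon),
               div_rate_eps0 = stem_diversification_rate(n_sp, ages[fam], 0),
               mean_range_km2 = mean(tot), mean_tropical_km2 = mean(trp),
               mean_temperate_km2 = mean(tmp),
               hort_prop = horticultural_use(
                 sum(species$horticultural[species$family == fam]), n_sp),
               stringsAsFactors = FALSE)
  })
  fam_data <- do.call(rbind, metrics)

  # latent naturalization score on the sqrt scale
  tmap <- default_transforms()
  Xs <- vapply(names(config$beta), function(col)
    standardize(transform_values(fam_data[[col]], tmap[[col]])),
    numeric(nrow(fam_data)))
  sub <- prune_phylogeny(tree, passing)
  u <- brownian_effects(sub, config$sigma2_p,
                        seed = component_seed(seed, "brownian"))[fam_data$family]
  lin <- config$mu0 + drop(Xs %*% config$beta) + u
  e <- stats::rnorm(nrow(fam_data), 0, sqrt(config$sigma2_e))
  s <- lin + e
  tries <- 0
  while (any(s <= 0.05) && tries < 100) {
    bad <- which(s <= 0.05)
    e[bad] <- stats::rnorm(length(bad), 0, sqrt(config$sigma2_e))
    s <- lin + e
    tries <- tries + 1
  }
  if (any(s <= 0.05)) {
    stop("inverse construction infeasible after 100 resamples (latent score <= 0)",
         call. = FALSE)
  }
  if (tries > 0) message(sprintf("resampled %d negative latent draw round(s)", tries))

  # invert the index to integer counts: n_nat * records = s^2 * n_species
  n_sp <- fam_data$n_species
  target <- s^2 * n_sp
  n_nat <- as.integer(pmin(pmax(round(sqrt(target)), 1), n_sp))
  records <- as.integer(pmax(n_nat, round(target / n_nat)))

  nat_rows <- vector("list", nrow(fam_data))
  for (i in seq_len(nrow(fam_data))) {
    fam <- fam_data$family[i]
    ids <- species$species_id[species$family == fam]
    nat_sp <- sample(ids, n_nat[i])
    extra <- records[i] - n_nat[i]
    counts <- rep(1L, n_nat[i])
    if (extra > 0) {
      counts <- counts + drop(stats::rmultinom(1, extra, rep(1, n_nat[i])))
    }
    counts <- pmin(counts, nrow(regions))
    nat_rows[[i]] <- data.frame(
      species_id = rep(nat_sp, counts),
      region_id = regions$region_id[unlist(lapply(counts, function(k)
        sample(nrow(regions), k)))],
      status = "naturalized",
      stringsAsFactors = FALSE
    )
  }
  naturalized <- do.call(rbind, nat_rows)
  achieved_records <- vapply(seq_len(nrow(fam_data)), function(i)
    sum(naturalized$species_id %in%
          species$species_id[species$family == fam_data$family[i]]),
    integer(1))

  fam_data$n_naturalized <- n_nat
  fam_data$naturalized_region_records <- achieved_records
  fam_data$nat_success <- mapply(naturalization_success, n_nat, n_sp,
                                 achieved_records)

  occurrences <- rbind(native, naturalized)
  rownames(occurrences) <- NULL
  rownames(fam_data) <- NULL

  list(species = species,
       occurrences = occurrences,
       family_data = fam_data,
       truth = list(beta = config$beta, mu0 = config$mu0,
                    sigma2_p = config$sigma2_p, sigma2_e = config$sigma2_e,
                    u = u, latent = s,
                    achieved_sqrt_response = sqrt(fam_data$nat_success),
                    r_true = stats::setNames(r_true, fams),
                    richness = stats::setNames(richness, fams),
                    passing = passing))
}

#' Simulate a complete input bundle
#'
#' Tree + regions + species tables from one master seed (components split
#' via \code{\link{component_seed}}).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list: \code{tree}, \code{regions}, plus everything returned by
#'   \code{\link{simulate_species_tables}}, and the config echo.
#' @export
simulate_study <- function(config = simulation_config()) {
  tree <- simulate_tree(config$n_families, config$birth, config$death,
                        seed = component_seed(config$seed, "tree"))
  regions <- simulate_regions(config$n_regions, config$area_meanlog,
                              config$area_sdlog, config$trop_shape1,
                              config$trop_shape2,
                              seed = component_seed(config$seed, "regions"))
  tabs <- simulate_species_tables(tree, regions, config,
                                  seed = component_seed(config$seed, "species"))
  c(list(tree = tree, regions = regions, config = config), tabs)
}

#' Write / read a simulation bundle as plain-text files
#'
#' Newick tree, three CSVs, and a ground-truth JSON in one directory --
#' the on-disk fixture format for the whole pipeline.
#'
#' @param bundle result of \code{\link{simulate_study}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly (write) / the reconstructed bundle (read).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(bundle$tree), file.path(dir, "tree.nwk"))
  utils::write.csv(bundle$regions, file.path(dir, "regions.csv"), row.names = FALSE)
  utils::write.csv(bundle$species, file.path(dir, "species.csv"), row.names = FALSE)
  utils::write.csv(bundle$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  truth <- bundle$truth
  truth$beta <- as.list(truth$beta)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  list(
    tree = read_newick(paste(readLines(file.path(dir, "tree.nwk")), collapse = "")),
    regions = utils::read.csv(file.path(dir, "regions.csv"), stringsAsFactors = FALSE),
    species = utils::read.csv(file.path(dir, "species.csv"), stringsAsFactors = FALSE),
    occurrences = utils::read.csv(file.path(dir, "occurrences.csv"),
                                  stringsAsFactors = FALSE),
    truth = jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  )
}
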