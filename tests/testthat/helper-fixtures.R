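# Shared fixtures and independent oracles, all built in code.

# Brute-force phylogenetic correlation: enumerate the root path of every tip
# as a set of edge indices; shared history of (i, j) is the summed length of
# the common edges. Independent of ape::vcv.
bf_phylo_corr <- function(tree) {
  n <- length(tree$tip.label)
  paths <- lapply(seq_len(n), function(i) {
    edges <- integer(0); node <- i
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      edges <- c(edges, e); node <- tree$edge[e, 1]
    }
    edges
  })
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(tree$edge.length[shared])
  }
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V / sqrt(outer(diag(V), diag(V)))
}

# Hand-designed species/occurrence/region fixture exercising every branch of
# the family inclusion filter.
make_filter_fixture <- function() {
  regions <- data.frame(
    region_id = c("R1", "R2"),
    area_km2 = c(100, 200),
    tropical_km2 = c(60, 0),
    temperate_km2 = c(40, 200),
    stringsAsFactors = FALSE
  )
  mk <- function(fam, n, accepted = TRUE, hort_n = 0) {
    data.frame(
      species_id = sprintf("%s_s%02d", fam, seq_len(n)),
      family = fam, order = paste0("Ord_", substr(fam, 4, 4)),
      accepted = accepted,
      horticultural = seq_len(n) <= hort_n,
      coverage_flag = ifelse(seq_len(n) %% 5 == 0, "partial", "complete"),
      stringsAsFactors = FALSE
    )
  }
  species <- rbind(
    mk("FamA", 50, hort_n = 10),                   # retained
    mk("FamB", 49),                                # min_richness
    mk("FamC", 50),                                # not in tree
    mk("FamD", 50),                                # no native records
    mk("FamF", 50),                                # no stem age supplied
    rbind(mk("FamE", 45), mk("FamE", 10, accepted = FALSE))  # accepted 45
  )
  # FamE ids collide between the two mk() calls; make them unique
  species$species_id <- make.unique(species$species_id)

  native <- function(fam, n, region) {
    ids <- species$species_id[species$family == fam & species$accepted][seq_len(n)]
    data.frame(species_id = ids, region_id = region, status = "native",
               stringsAsFactors = FALSE)
  }
  occ <- rbind(
    native("FamA", 50, "R1"),
    native("FamC", 50, "R1"),
    native("FamF", 50, "R2"),
    native("FamE", 45, "R2"),
    # FamA: 5 naturalized species, 12 (species, region) records in total
    data.frame(
      species_id = rep(sprintf("FamA_s%02d", 1:5), c(3, 3, 2, 2, 2)),
      region_id = rep(c("R1", "R2"), 6),
      status = "naturalized", stringsAsFactors = FALSE)
  )
  tree <- read_newick("((FamA:50,FamB:50):50,(FamD:60,(FamF:30,FamE:30):30):40);")
  ages <- c(FamA = 50, FamB = 50, FamD = 60, FamE = 30)  # FamF deliberately absent
  list(species = species, occurrences = occ, regions = regions,
       tree = tree, ages = ages)
}

# Minimal hand-built fit object for summary/DIC unit tests.
make_fake_fit <- function(chains, p, ytil, Xtil, u_mean_til = NULL) {
  labels <- setdiff(colnames(chains[[1]]), "deviance")
  structure(list(
    chains = chains, labels = labels, p = p,
    ytil = ytil, Xtil = Xtil,
    u_mean_til = if (is.null(u_mean_til)) rep(0, length(ytil)) else u_mean_til,
    u_mean = if (is.null(u_mean_til)) rep(0, length(ytil)) else u_mean_til,
    n = length(ytil),
    settings = mcmc_settings(n_iter = nrow(chains[[1]]), burn_in = 0, thin = 1,
                             n_chains = length(chains)),
    priors = prior_spec()
  ), class = "natdiv_fit")
}

# Tiny ready-made study bundle for pipeline tests (kept small for speed).
small_bundle <- function(seed = 11, n_families = 40, n_regions = 40) {
  cfg <- simulation_config(n_families = n_families, n_regions = n_regions,
                           max_richness = 300, seed = seed)
  suppressMessages(simulate_study(cfg))
}

fast_settings <- function(seed = 1, n_chains = 2) {
  mcmc_settings(n_iter = 4000, burn_in = 1000, thin = 10,
                n_chains = n_chains, seed = seed)
}
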