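#' Method-of-moments net diversification rate for stem clades
#'
#' Estimates the net diversification rate r = lambda - mu of a clade from its
#' extant species richness \code{n} and stem age \code{t}, under an assumed
#' relative extinction fraction epsilon = mu/lambda:
#' \deqn{r = \log(n (1 - \epsilon) + \epsilon) / t}
#' With epsilon = 0 this collapses to log(n)/t; a clade of one species has
#' rate 0 at any epsilon.
#'
#' @param n extant species richness (integer-valued, >= 1); vectorized.
#' @param t stem age in Myr (> 0); vectorized.
#' @param epsilon relative extinction in [0, 1).
#' @return net diversification rate(s), per Myr.
#' @export
stem_diversification_rate <- function(n, t, epsilon = 0.9) {
  if (anyNA(n) || anyNA(t) || anyNA(epsilon) ||
      any(!is.finite(n)) || any(!is.finite(t)) || any(!is.finite(epsilon))) {
    stop("non-finite arguments", call. = FALSE)
  }
  if (any(abs(n - round(n)) > 1e-8)) stop("n must be integer-valued", call. = FALSE)
  if (any(n < 1)) stop("richness n must be >= 1", call. = FALSE)
  if (any(t <= 0)) stop("stem age t must be > 0", call. = FALSE)
  if (any(epsilon < 0 | epsilon >= 1)) stop("epsilon must be in [0, 1)", call. = FALSE)
  log(n * (1 - epsilon) + epsilon) / t
}

#' Cumulative native range size of a species
#'
#' The species range is the summed area of all region polygons where the
#' species is recorded as native; 0 if it has no native-region records.
#'
#' @param native_regions character vector of region ids occupied by the species.
#' @param regions region table (see \code{\link{validate_region_table}}).
#' @return range size in km^2.
#' @export
species_range_size <- function(native_regions, regions) {
  idx <- match_regions(native_regions, regions)
  sum(regions$area_km2[idx])
}

#' Tropical and temperate components of a species range
#'
#' @inheritParams species_range_size
#' @return named numeric vector \code{c(tropical_km2, temperate_km2)}; the
#'   components sum to the total range size.
#' @export
species_zonal_range <- function(native_regions, regions) {
  idx <- match_regions(native_regions, regions)
  c(tropical_km2 = sum(regions$tropical_km2[idx]),
    temperate_km2 = sum(regions$temperate_km2[idx]))
}

match_regions <- function(region_ids, regions) {
  if (length(region_ids) == 0L) return(integer(0))
  idx <- match(as.character(region_ids), regions$region_id)
  if (anyNA(idx)) {
    stop("unknown region id(s): ",
         paste(region_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Validate a region table
#'
#' Checks the contract of the region table: unique ids, positive total areas,
#' non-negative zonal areas, and tropical + temperate = total (1e-6 relative).
#'
#' @param regions data.frame with columns \code{region_id}, \code{area_km2},
#'   \code{tropical_km2}, \code{temperate_km2}.
#' @return the table, invisibly.
#' @export
validate_region_table <- function(regions) {
  need <- c("region_id", "area_km2", "tropical_km2", "temperate_km2")
  miss <- setdiff(need, names(regions))
  if (length(miss)) stop("region table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(regions$region_id)) stop("duplicate region ids", call. = FALSE)
  if (any(regions$area_km2 <= 0)) stop("region areas must be > 0", call. = FALSE)
  if (any(regions$tropical_km2 < 0) || any(regions$temperate_km2 < 0)) {
    stop("zonal areas must be >= 0", call. = FALSE)
  }
  rel <- abs(regions$tropical_km2 + regions$temperate_km2 - regions$area_km2) /
    regions$area_km2
  if (any(rel > 1e-6)) {
    stop("tropical + temperate != total area for region(s): ",
         paste(regions$region_id[rel > 1e-6], collapse = ", "), call. = FALSE)
  }
  invisible(regions)
}

#' Per-species range sizes for a family, by zone or coverage subset
#'
#' Returns the vector of species range sizes for one family, optionally
#' restricted to a climatic zone (\code{"tropical"}/\code{"temperate"}) or to
#' a data-coverage subset (\code{"global_coverage"}: species whose global
#' distribution is completely recorded; \code{"partial_coverage"}: the rest).
#' Species with no native-region records are excluded (a missing distribution
#' is not a zero range).
#'
#' @param family family label.
#' @param species species table (one row per species; see
#'   \code{\link{build_family_dataset}} for the column contract).
#' @param occurrences long occurrence table (\code{species_id},
#'   \code{region_id}, \code{status}).
#' @param regions region table.
#' @param zone one of \code{"all"}, \code{"tropical"}, \code{"temperate"}.
#' @param subset one of \code{"all"}, \code{"global_coverage"},
#'   \code{"partial_coverage"} (requires a \code{coverage_flag} column with
#'   values \code{"complete"}/\code{"partial"}).
#' @return numeric vector of per-species range sizes (km^2), named by species.
#' @export
family_range_sizes <- function(family, species, occurrences, regions,
                               zone = c("all", "tropical", "temperate"),
                               subset = c("all", "global_coverage", "partial_coverage")) {
  zone <- match.arg(zone)
  subset <- match.arg(subset)
  sp <- species[species$family == family & species$accepted, , drop = FALSE]
  if (subset != "all") {
    if (is.null(sp$coverage_flag)) stop("coverage_flag column required for coverage subsets", call. = FALSE)
    want <- if (subset == "global_coverage") "complete" else "partial"
    sp <- sp[sp$coverage_flag == want, , drop = FALSE]
  }
  nat <- occurrences[occurrences$status == "native" &
                       occurrences$species_id %in% sp$species_id, , drop = FALSE]
  if (nrow(nat) == 0L) return(stats::setNames(numeric(0), character(0)))
  per_species <- split(nat$region_id, nat$species_id)
  col <- switch(zone, all = "area_km2", tropical = "tropical_km2",
                temperate = "temperate_km2")
  vapply(per_species, function(rids) {
    idx <- match_regions(unique(rids), regions)
    sum(regions[[col]][idx])
  }, numeric(1))
}

#' Mean family range size
#'
#' Arithmetic mean of per-species cumulative range sizes over the family's
#' species with at least one native-region record.
#'
#' @inheritParams family_range_sizes
#' @return mean range in km^2, or \code{NA_real_} if no species has
#'   distribution data (the family is dropped later at the merge).
#' @export
mean_family_range <- function(family, species, occurrences, regions,
                              zone = c("all", "tropical", "temperate")) {
  zone <- match.arg(zone)
  sizes <- family_range_sizes(family, species, occurrences, regions, zone = zone)
  if (length(sizes) == 0L) return(NA_real_)
  mean(sizes)
}

#' Naturalization success index of a family
#'
#' The response variable of the analysis: the proportion of a family's
#' species that have naturalized anywhere, multiplied by the family's total
#' count of naturalized (species, region) records. It rewards both how many
#' species escaped and how widely they spread.
#'
#' @param n_nat number of naturalized species in the family.
#' @param n_total total (accepted) species in the family, >= 1.
#' @param region_records summed number of regions each naturalized species is
#'   naturalized in (not deduplicated across species).
#' @return index >= 0.
#' @export
naturalization_success <- function(n_nat, n_total, region_records) {
  if (n_total < 1) stop("n_total must be >= 1", call. = FALSE)
  if (n_nat < 0 || n_nat > n_total) {
    stop("data inconsistency: n_nat must be in [0, n_total]", call. = FALSE)
  }
  if (n_nat > 0 && region_records < n_nat) {
    stop("data inconsistency: region_records < n_nat", call. = FALSE)
  }
  if (n_nat == 0) return(0)
  (n_nat / n_total) * region_records
}

#' Proportion of a family's species in horticultural use
#'
#' @param n_hort number of horticulturally used species.
#' @param n_total total (accepted) species, >= 1.
#' @return proportion in [0, 1].
#' @export
horticultural_use <- function(n_hort, n_total) {
  if (n_total < 1) stop("n_total must be >= 1", call. = FALSE)
  if (n_hort < 0 || n_hort > n_total) {
    stop("data inconsistency: n_hort must be in [0, n_total]", call. = FALSE)
  }
  n_hort / n_total
}

#' Assemble the family-level analysis table
#'
#' Merges the species checklist, occurrence records, region areas, phylogeny
#' and stem ages into one row per family, applying the inclusion filter:
#' a family is retained iff it has >= \code{min_richness} accepted species,
#' is a tip of the tree, has a stem age, and has at least one species with
#' native-range data. Exclusions are returned with the first failing
#' criterion per family.
#'
#' @param species data.frame: \code{species_id}, \code{family}, \code{order},
#'   \code{accepted} (logical), \code{horticultural} (logical), optional
#'   \code{coverage_flag}.
#' @param occurrences data.frame: \code{species_id}, \code{region_id},
#'   \code{status} in \{"native", "naturalized"\}.
#' @param regions region table.
#' @param tree \code{phylo} object with family tips.
#' @param ages named stem-age vector (Myr); defaults to \code{stem_ages(tree)}.
#' @param epsilon relative extinction for the reported diversification rate
#'   (default 0.9; the epsilon = 0 rate is always reported alongside).
#' @param min_richness minimum accepted richness (default 50).
#' @return list with \code{data} (the family dataset, one row per retained
#'   family) and \code{excluded} (data.frame family/reason).
#' @export
build_family_dataset <- function(species, occurrences, regions, tree,
                                 ages = NULL, epsilon = 0.9, min_richness = 50) {
  validate_region_table(regions)
  validate_phylogeny(tree)
  if (is.null(ages)) ages <- stem_ages(tree)
  sp <- species[species$accepted, , drop = FALSE]
  if (any(!nzchar(sp$family))) stop("accepted species with empty family", call. = FALSE)
  if (anyDuplicated(species$species_id)) stop("duplicate species ids", call. = FALSE)

  fams <- sort(unique(sp$family))
  nat_occ <- occurrences[occurrences$status == "naturalized", , drop = FALSE]
  bad <- setdiff(unique(occurrences$region_id), regions$region_id)
  if (length(bad)) stop("unknown region id(s) in occurrences: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  rows <- list(); excluded <- list()
  for (fam in fams) {
    fsp <- sp[sp$family == fam, , drop = FALSE]
    n_species <- nrow(fsp)
    if (n_species < min_richness) {
      excluded[[fam]] <- "min_richness"; next
    }
    if (!(fam %in% tree$tip.label)) {
      excluded[[fam]] <- "no_phylogeny"; next
    }
    if (!(fam %in% names(ages)) || is.na(ages[[fam]])) {
      excluded[[fam]] <- "no_stem_age"; next
    }
    sizes <- family_range_sizes(fam, species, occurrences, regions)
    if (length(sizes) == 0L) {
      excluded[[fam]] <- "no_range_data"; next
    }
    zon_t <- family_range_sizes(fam, species, occurrences, regions, zone = "tropical")
    zon_m <- family_range_sizes(fam, species, occurrences, regions, zone = "temperate")

    fam_nat <- nat_occ[nat_occ$species_id %in% fsp$species_id, , drop = FALSE]
    nat_sp <- unique(fam_nat$species_id)
    n_naturalized <- length(nat_sp)
    region_records <- nrow(fam_nat)

    ord <- unique(fsp$order)
    rows[[fam]] <- data.frame(
      family = fam,
      order = if (length(ord)) ord[1] else NA_character_,
      n_species = n_species,
      n_naturalized = n_naturalized,
      naturalized_region_records = region_records,
      stem_age = unname(ages[[fam]]),
      div_rate = stem_diversification_rate(n_species, ages[[fam]], epsilon),
      div_rate_eps0 = stem_diversification_rate(n_species, ages[[fam]], 0),
      mean_range_km2 = mean(sizes),
      mean_tropical_km2 = mean(zon_t),
      mean_temperate_km2 = mean(zon_m),
      hort_prop = horticultural_use(sum(fsp$horticultural), n_species),
      nat_success = naturalization_success(n_naturalized, n_species, region_records),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) stop("no family passed the inclusion filter", call. = FALSE)
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  excl <- data.frame(family = names(excluded),
                     reason = unlist(excluded, use.names = FALSE),
                     stringsAsFactors = FALSE)
  if (nrow(excl)) {
    message(sprintf("excluded %d famil%s: %s", nrow(excl),
                    if (nrow(excl) == 1) "y" else "ies",
                    paste(sprintf("%s (%s)", excl$family, excl$reason), collapse = ", ")))
  }
  list(data = data, excluded = excl)
}
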