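#' Run the full family-level naturalization analysis
#'
#' Orchestrates every stage on an input bundle (in-memory or on disk):
#' family-table construction with the inclusion filter, predictor
#' correlation audit, PGLMM fits for the requested models, convergence
#' diagnostics, optional DIC stepwise selection, and CSV/JSON outputs.
#' All randomness flows from \code{seed}; identical config + seed gives
#' identical outputs.
#'
#' @param bundle a simulation bundle (\code{\link{simulate_study}} /
#'   \code{\link{read_bundle}}) or a list with \code{tree}, \code{regions},
#'   \code{species}, \code{occurrences}.
#' @param models character subset of \code{c("model1","model2","model3")}.
#' @param epsilon relative extinction for the diversification rate.
#' @param min_richness inclusion filter.
#' @param priors a \code{\link{prior_spec}}.
#' @param settings a \code{\link{mcmc_settings}} (its \code{seed} drives the
#'   chains).
#' @param select run DIC stepwise selection over the model-1 candidates.
#' @param outdir optional output directory for CSVs and the manifest.
#' @return list: \code{family_data}, \code{excluded}, \code{correlations},
#'   \code{fits}, \code{summaries}, \code{convergence}, \code{selection}
#'   (or NULL), \code{converged} (all requested models pass PSRF < 1.1).
#' @export
run_pipeline <- function(bundle, models = c("model1", "model2", "model3"),
                         epsilon = 0.9, min_richness = 50,
                         priors = prior_spec(),
                         settings = mcmc_settings(reduced = TRUE),
                         select = FALSE, outdir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  built <- build_family_dataset(bundle$species, bundle$occurrences,
                                bundle$regions, bundle$tree,
                                epsilon = epsilon, min_richness = min_richness)
  data <- built$data
  tree <- prune_phylogeny(bundle$tree, data$family)
  A <- phylo_covariance(tree, order = data$family)

  fits <- list(); summaries <- list(); convergence <- list()
  corr <- NULL
  for (mod in models) {
    spec <- model_spec(mod)
    d <- build_design(data, spec)
    if (is.null(corr)) {
      corr <- predictor_correlations(d$X[, -1, drop = FALSE])
    }
    fit <- gibbs_fit(d$y, d$X, A, priors = priors, settings = settings)
    fits[[mod]] <- fit
    summaries[[mod]] <- posterior_summary(fit)
    convergence[[mod]] <- gelman_rubin(fit)
  }

  selection <- NULL
  if (select) {
    spec1 <- model_spec("model1")
    selection <- stepwise_selection(
      data, A, candidates = setdiff(spec1$effects, "div_rate"),
      priors = priors, settings = settings)
  }

  converged <- all(vapply(convergence, `[[`, logical(1), "pass"))
  result <- list(family_data = data, excluded = built$excluded,
                 correlations = corr, fits = fits, summaries = summaries,
                 convergence = convergence, selection = selection,
                 converged = converged, models = models,
                 settings = settings, priors = priors)
  if (!is.null(outdir)) write_report(result, outdir)
  result
}

#' Write the pipeline report bundle to disk
#'
#' Family dataset, per-model posterior summaries, convergence report,
#' correlation matrix, optional selection table, the combined report table,
#' and a JSON manifest with settings and content hashes of every written
#' file (dependency-free FNV-1a hash).
#'
#' @param result a \code{\link{run_pipeline}} result.
#' @param outdir output directory.
#' @return named vector of written file paths, invisibly.
#' @export
write_report <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(result$family_data, "family_dataset.csv")
  if (nrow(result$excluded)) wr(result$excluded, "excluded_families.csv")
  corr <- result$correlations$correlations
  wr(data.frame(predictor = rownames(corr), corr, check.names = FALSE),
     "predictor_correlations.csv")
  for (mod in result$models) {
    wr(result$summaries[[mod]], sprintf("summary_%s.csv", mod))
  }
  conv <- do.call(rbind, lapply(result$models, function(mod) {
    cv <- result$convergence[[mod]]
    data.frame(model = mod, parameter = c(names(cv$psrf), "multivariate"),
               psrf = c(cv$psrf, cv$mpsrf),
               pass = cv$pass, stringsAsFactors = FALSE)
  }))
  wr(conv, "convergence.csv")
  if (!is.null(result$selection)) wr(result$selection, "dic_selection.csv")
  wr(report_table(result$summaries), "report_table.csv")

  manifest <- list(
    models = result$models,
    settings = unclass(result$settings),
    priors = unclass(result$priors),
    converged = result$converged,
    n_families = nrow(result$family_data),
    hashes = lapply(paths, function(p) fnv1a_hash(readBin(p, "raw", file.size(p))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(unlist(paths))
}

# Polynomial rolling content hash over the file bytes, kept in exact-integer
# double range; library-free so the manifest needs no digest package.
fnv1a_hash <- function(raw_bytes) {
  h <- 5381
  for (b in as.integer(raw_bytes)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Combined report table across models
#'
#' One row per predictor per model (long layout mirroring a three-model
#' results table): posterior mean, 95% HPD bounds, effective sample size,
#' floor-formatted pMCMC, and a significance flag at pMCMC < 0.05.
#'
#' @param summaries named list of \code{\link{posterior_summary}} tables.
#' @return data.frame.
#' @export
report_table <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  out <- do.call(rbind, lapply(names(summaries), function(mod) {
    s <- summaries[[mod]]
    s <- s[!(s$parameter %in% c("sigma2_p", "sigma2_e")), , drop = FALSE]
    data.frame(model = mod, predictor = s$parameter,
               post_mean = s$post_mean, lower = s$lower, upper = s$upper,
               eff_samp = s$eff_samp, pMCMC = s$pMCMC_fmt,
               significant = !is.na(s$pMCMC) & s$pMCMC < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
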