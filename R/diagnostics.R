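#' Gelman-Rubin convergence diagnostics
#'
#' Potential scale reduction factors from >= 2 chains of equal length:
#' per parameter, with between-chain variance B and mean within-chain
#' variance W,
#' \deqn{PSRF^2 = (n-1)/n + \frac{m+1}{m n} \frac{B}{W}}
#' and the multivariate factor from the largest eigenvalue of
#' \eqn{W^{-1} B / n} (Brooks-Gelman). Convergence is declared when the
#' multivariate PSRF is below the threshold (1.1 by default).
#'
#' @param chains a \code{natdiv_fit} or a list of equal-dimension draw
#'   matrices (rows = draws, columns = parameters).
#' @param threshold convergence threshold on the multivariate PSRF.
#' @return a \code{natdiv_convergence} list: \code{psrf} (named per-parameter
#'   vector), \code{mpsrf}, \code{pass}, \code{ess}.
#' @export
gelman_rubin <- function(chains, threshold = 1.1) {
  if (inherits(chains, "natdiv_fit")) {
    fit <- chains
    chains <- lapply(fit$chains, function(m) m[, fit$labels, drop = FALSE])
  }
  m <- length(chains)
  if (m < 2) stop("need >= 2 chains", call. = FALSE)
  dims <- vapply(chains, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("chains must have equal dimensions", call. = FALSE)
  }
  n <- dims[1, 1]
  if (n < 10) stop("need >= 10 draws per chain", call. = FALSE)
  k <- dims[2, 1]
  labels <- colnames(chains[[1]])
  if (is.null(labels)) labels <- paste0("par", seq_len(k))

  means <- matrix(vapply(chains, colMeans, numeric(k)),     # m x k
                  nrow = m, ncol = k, byrow = TRUE)
  W_mats <- lapply(chains, stats::cov)
  W <- Reduce(`+`, W_mats) / m                              # k x k
  w_diag <- diag(as.matrix(W))
  if (any(w_diag <= 0)) {
    stop("degenerate chain: zero within-chain variance for ",
         paste(labels[w_diag <= 0], collapse = ", "), call. = FALSE)
  }
  B <- n * stats::cov(means)                                # k x k
  b_diag <- diag(as.matrix(B))

  psrf <- sqrt((n - 1) / n + (m + 1) / (m * n) * b_diag / w_diag)
  if (k == 1) {
    mpsrf <- psrf[1]
  } else {
    lam1 <- max(Re(eigen(solve(W, B) / n, only.values = TRUE)$values))
    mpsrf <- sqrt((n - 1) / n + (m + 1) / m * lam1)
  }
  ess <- pmin(Reduce(`+`, lapply(chains, function(x) apply(x, 2, .ess_one))), m * n)
  structure(list(psrf = stats::setNames(psrf, labels),
                 mpsrf = unname(mpsrf),
                 threshold = threshold,
                 pass = unname(mpsrf) < threshold,
                 ess = stats::setNames(ess, labels)),
            class = "natdiv_convergence")
}

#' @export
print.natdiv_convergence <- function(x, ...) {
  cat("Gelman-Rubin diagnostics\n")
  cat(sprintf("  multivariate PSRF: %.4f (%s at threshold %.2f)\n",
              x$mpsrf, if (x$pass) "PASS" else "FAIL", x$threshold))
  print(round(x$psrf, 4))
  invisible(x)
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with Dbar the posterior mean deviance (deviance is
#' recorded at every retained draw during sampling) and pD = Dbar - D(theta
#' bar), the plug-in deviance at the posterior means of (beta, u, sigma2_e).
#'
#' @param fit a \code{natdiv_fit}.
#' @return list(DIC, pD, mean_deviance, deviance_at_mean).
#' @export
dic <- function(fit) {
  dev <- pooled_draws(fit, include_deviance = TRUE)[, "deviance"]
  if (!all(is.finite(dev))) stop("non-finite deviance among retained draws", call. = FALSE)
  d_bar <- mean(dev)
  draws <- pooled_draws(fit)
  beta_bar <- colMeans(draws[, seq_len(fit$p), drop = FALSE])
  s2e_bar <- mean(draws[, "sigma2_e"])
  resid <- fit$ytil - drop(fit$Xtil %*% beta_bar) - fit$u_mean_til
  sse <- sum(resid^2)
  d_hat <- fit$n * (log(2 * pi) + log(s2e_bar)) + sse / s2e_bar
  if (!is.finite(d_hat)) stop("non-finite deviance at the posterior mean", call. = FALSE)
  pD <- d_bar - d_hat
  list(DIC = d_bar + pD, pD = pD, mean_deviance = d_bar, deviance_at_mean = d_hat)
}

#' DIC-based stepwise model selection
#'
#' Fits the PGLMM for every subset of the candidate predictors, always
#' including the base effect (diversification rate), and ranks the models by
#' DIC (ascending: lower is preferred). Selection runs default to the
#' reduced MCMC settings; refit the winners at full settings.
#'
#' @param data family dataset.
#' @param A phylogenetic correlation matrix ordered as \code{data$family}.
#' @param candidates character vector of candidate effect columns.
#' @param base_effect always-included effect (default \code{"div_rate"}).
#' @param response response column (default \code{"nat_success"}).
#' @param transforms transform map (default \code{\link{default_transforms}}).
#' @param priors,settings passed to \code{\link{gibbs_fit}};
#'   \code{settings} defaults to \code{mcmc_settings(reduced = TRUE)}.
#' @return data.frame (model, effects, DIC, pD, mean_deviance, converged?,
#'   error) sorted by DIC; failed fits are kept with an annotation.
#' @export
stepwise_selection <- function(data, A, candidates, base_effect = "div_rate",
                               response = "nat_success",
                               transforms = default_transforms(),
                               priors = prior_spec(),
                               settings = mcmc_settings(reduced = TRUE)) {
  subsets <- unlist(lapply(0:length(candidates), function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(extra) {
    effects <- c(base_effect, extra)
    spec <- list(name = "custom", response = response, effects = effects,
                 interactions = list(), transforms = transforms)
    label <- paste(effects, collapse = " + ")
    res <- tryCatch({
      d <- build_design(data, spec)
      fit <- gibbs_fit(d$y, d$X, A, priors = priors, settings = settings)
      ic <- dic(fit)
      data.frame(model = label, n_effects = length(effects),
                 DIC = ic$DIC, pD = ic$pD, mean_deviance = ic$mean_deviance,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(model = label, n_effects = length(effects),
                 DIC = NA_real_, pD = NA_real_, mean_deviance = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$DIC, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
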