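#' Prior specification for the PGLMM
#'
#' Weakly informative scalar inverse-Wishart priors on both variance
#' components, parameterized as in the animal-model literature: a scalar
#' inverse-Wishart(V, nu) is the inverse-gamma(nu/2, nu*V/2) distribution.
#' Fixed effects get an effectively flat Normal(0, beta_var) prior.
#'
#' @param V prior scale of each variance component (default 1).
#' @param nu prior degree of belief (default 0.002).
#' @param beta_var prior variance of each fixed-effect coefficient
#'   (default 1e10).
#' @return a \code{natdiv_prior} list.
#' @export
prior_spec <- function(V = 1, nu = 0.002, beta_var = 1e10) {
  stopifnot(V > 0, nu > 0, beta_var > 0)
  structure(list(V = V, nu = nu, beta_var = beta_var), class = "natdiv_prior")
}

#' MCMC settings
#'
#' Defaults follow the full analysis protocol: 520 000 iterations, burn-in
#' 20 000, thinning 100, three chains -- 5000 retained draws per chain.
#' \code{reduced = TRUE} gives the scaled-down settings used for model
#' selection runs (52 000 / 2000 / 10, same retained count).
#'
#' @param n_iter total iterations per chain.
#' @param burn_in discarded initial iterations.
#' @param thin thinning interval.
#' @param n_chains number of chains.
#' @param seed integer seed; chain c uses \code{seed + c - 1}.
#' @param reduced use the reduced selection-run settings as defaults.
#' @return a \code{natdiv_mcmc_settings} list.
#' @export
mcmc_settings <- function(n_iter = if (reduced) 52000 else 520000,
                          burn_in = if (reduced) 2000 else 20000,
                          thin = if (reduced) 10 else 100,
                          n_chains = 3, seed = 1, reduced = FALSE) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1)
  if ((n_iter - burn_in) %% thin != 0) {
    stop("(n_iter - burn_in) must be a multiple of thin", call. = FALSE)
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "natdiv_mcmc_settings")
}

#' Fit the phylogenetic mixed model by Gibbs sampling
#'
#' Samples the posterior of the Gaussian mixed model
#' \deqn{y = X\beta + u + e, \quad u \sim N(0, \sigma^2_p A), \quad
#'       e \sim N(0, \sigma^2_e I)}
#' where \code{A} is the phylogenetic correlation matrix (or any symmetric
#' PSD structure). The sampler works in the eigenbasis of \code{A}, drawing
#' (beta, u) as one exact Gaussian block per sweep (beta from its
#' u-marginalized conditional, then u | beta), and the two variance
#' components from their inverse-gamma full conditionals.
#'
#' Chains are overdispersed: chain c scales the initial variances by
#' 0.1 / 1 / 10 cyclically, with beta started at the least-squares solution.
#' Identical seed and settings give bit-identical chains.
#'
#' @param y numeric response vector.
#' @param X design matrix (include the intercept column).
#' @param A symmetric PSD random-effect covariance (n x n), e.g. from
#'   \code{\link{phylo_covariance}}. Eigenvalues below 1e-8 are lifted to
#'   1e-8 (a logged diagonal jitter) unless \code{psd_mode = "truncate"},
#'   which instead pins those directions of u at zero (used for
#'   rank-deficient group structures).
#' @param priors a \code{\link{prior_spec}}.
#' @param settings a \code{\link{mcmc_settings}}.
#' @param psd_mode \code{"jitter"} or \code{"truncate"}.
#' @param fix_variances optional list(sigma2_p, sigma2_e) freezing the
#'   variance updates (used for conjugate-oracle validation).
#' @return a \code{natdiv_fit} object: per-chain draw matrices (columns =
#'   fixed effects, sigma2_p, sigma2_e, deviance), posterior mean of u,
#'   settings/prior echo, and the rotated data needed for DIC.
#' @export
gibbs_fit <- function(y, X, A, priors = prior_spec(), settings = mcmc_settings(),
                      psd_mode = c("jitter", "truncate"), fix_variances = NULL) {
  psd_mode <- match.arg(psd_mode)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) != length(y)", call. = FALSE)
  if (!is.matrix(A) || nrow(A) != n || ncol(A) != n) {
    stop("A must be an n x n matrix conforming with y", call. = FALSE)
  }
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric", call. = FALSE)

  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- eig$values
  if (min(lam) < -1e-8) {
    stop("A is not positive semidefinite (min eigenvalue ", format(min(lam)), ")",
         call. = FALSE)
  }
  if (psd_mode == "jitter") {
    n_low <- sum(lam < 1e-8)
    if (n_low > 0) {
      message(sprintf("lifting %d near-zero eigenvalue(s) of A to 1e-8 (diagonal jitter)", n_low))
      lam <- pmax(lam, 1e-8)
    }
  } else {
    lam <- pmax(lam, 0)
  }
  Q <- eig$vectors
  ytil <- drop(crossprod(Q, y))
  Xtil <- crossprod(Q, X)

  beta0 <- tryCatch(qr.solve(X, y), error = function(e)
    stop("singular least-squares start; consider rescaling predictors", call. = FALSE))
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  mult <- c(1, 0.1, 10)

  fixed <- !is.null(fix_variances)
  chains <- vector("list", settings$n_chains)
  u_means <- vector("list", settings$n_chains)
  xn <- colnames(X)
  if (is.null(xn)) xn <- character(ncol(X))
  xn[!nzchar(xn)] <- paste0("b", which(!nzchar(xn)))
  labels <- c(xn, "sigma2_p", "sigma2_e")

  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + ch - 1L)
    m <- mult[(ch - 1L) %% 3L + 1L]
    s2p0 <- if (fixed) fix_variances$sigma2_p else vy / 2 * m
    s2e0 <- if (fixed) fix_variances$sigma2_e else vy / 2 * m
    out <- .gibbs_core(ytil, Xtil, lam, beta0, s2p0, s2e0,
                       priors$nu, priors$V, priors$beta_var,
                       settings$n_iter, settings$burn_in, settings$thin,
                       fixed)
    colnames(out$draws) <- c(labels, "deviance")
    chains[[ch]] <- out$draws
    u_means[[ch]] <- drop(out$u_mean)
  }

  u_mean_til <- Reduce(`+`, u_means) / length(u_means)
  structure(list(
    chains = chains,
    labels = labels,
    u_mean = drop(Q %*% u_mean_til),
    u_mean_til = u_mean_til,
    ytil = ytil, Xtil = Xtil, lambda = lam, Q = Q,
    n = n, p = ncol(X),
    priors = priors, settings = settings,
    psd_mode = psd_mode,
    fix_variances = fix_variances
  ), class = "natdiv_fit")
}

#' Order-level GLMM validation variant
#'
#' Same sampler and contract as \code{\link{gibbs_fit}}, but the random
#' effect is a taxonomic-group effect: u_g ~ N(0, sigma2_g I) over groups
#' (plant orders), mapped through the family-to-order incidence matrix.
#' Implemented as \code{gibbs_fit} on the rank-deficient structure
#' \code{Z Z'} with zero eigen-directions truncated; the group quadratic
#' form u'u is recovered exactly through the pseudo-inverse.
#'
#' @param y,X,priors,settings as in \code{\link{gibbs_fit}}.
#' @param groups character/factor vector mapping each row (family) to its
#'   order; no NAs.
#' @return a \code{natdiv_fit}; the variance component labelled
#'   \code{sigma2_p} is the order-level variance, and \code{group_effects}
#'   holds the posterior-mean order effects.
#' @export
glmm_fit <- function(y, X, groups, priors = prior_spec(), settings = mcmc_settings()) {
  if (anyNA(groups)) stop("every family must map to one order", call. = FALSE)
  groups <- as.factor(groups)
  if (length(groups) != length(y)) stop("groups must conform with y", call. = FALSE)
  Z <- matrix(0, length(groups), nlevels(groups))
  Z[cbind(seq_along(groups), as.integer(groups))] <- 1
  fit <- gibbs_fit(y, X, tcrossprod(Z), priors = priors, settings = settings,
                   psd_mode = "truncate")
  counts <- colSums(Z)
  fit$group_effects <- stats::setNames(drop(crossprod(Z, fit$u_mean)) / counts,
                                       levels(groups))
  fit
}

#' Pool retained draws across chains
#'
#' @param fit a \code{natdiv_fit}.
#' @param include_deviance keep the deviance column.
#' @return matrix of pooled draws.
#' @export
pooled_draws <- function(fit, include_deviance = FALSE) {
  out <- do.call(rbind, fit$chains)
  if (!include_deviance) out <- out[, fit$labels, drop = FALSE]
  out
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing a \code{prob} fraction of the draws.
#'
#' @param x numeric draws.
#' @param prob coverage (default 0.95).
#' @return c(lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n < 2) return(c(lower = x[1], upper = x[1]))
  m <- max(1L, min(n - 1L, round(prob * n)))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Effective sample size from the autocorrelation time
#'
#' Spectral-density-at-zero estimate via an AIC-selected AR fit (the
#' standard time-series route): ESS = n * var(x) / spec0. Summed over
#' chains and capped at the total number of retained draws.
#'
#' @param fit_or_matrix a \code{natdiv_fit} or a draws matrix.
#' @return named vector of ESS per parameter.
#' @export
effective_size <- function(fit_or_matrix) {
  chains <- if (inherits(fit_or_matrix, "natdiv_fit")) {
    lapply(fit_or_matrix$chains, function(m)
      m[, fit_or_matrix$labels, drop = FALSE])
  } else list(as.matrix(fit_or_matrix))
  total <- sum(vapply(chains, nrow, integer(1)))
  ess <- Reduce(`+`, lapply(chains, function(m) apply(m, 2, .ess_one)))
  pmin(ess, total)
}

.ess_one <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(n)
  spec0 <- tryCatch({
    fit <- stats::ar(x, aic = TRUE, order.max = min(50, floor(n / 4)))
    if (length(fit$ar) == 0) v else fit$var.pred / (1 - sum(fit$ar))^2
  }, error = function(e) v)
  if (!is.finite(spec0) || spec0 <= 0) return(n)
  n * v / spec0
}

#' Posterior summary table
#'
#' Per parameter: posterior mean over the pooled post-burn-in draws, 95%
#' highest-posterior-density interval, effective sample size, and pMCMC =
#' 2 min(Pr(draw > 0), Pr(draw < 0)) floored at 2 / (total draws). pMCMC at
#' the floor is additionally formatted as "< floor". Variance components
#' (strictly positive by construction) get NA pMCMC.
#'
#' @param fit a \code{natdiv_fit}.
#' @param prob credible-interval coverage (default 0.95).
#' @param per_chain also return the per-chain summary list.
#' @return data.frame with columns parameter, post_mean, lower, upper,
#'   eff_samp, pMCMC, pMCMC_fmt.
#' @export
posterior_summary <- function(fit, prob = 0.95, per_chain = FALSE) {
  draws <- pooled_draws(fit)
  if (nrow(draws) < 2) stop("need >= 2 retained draws", call. = FALSE)
  tab <- .summarize_draws(draws, fit$labels, fit$p, prob)
  tab$eff_samp <- unname(effective_size(fit))
  if (per_chain) {
    attr(tab, "per_chain") <- lapply(fit$chains, function(m)
      .summarize_draws(m[, fit$labels, drop = FALSE], fit$labels, fit$p, prob))
  }
  tab
}

.summarize_draws <- function(draws, labels, p_fixed, prob) {
  n_draws <- nrow(draws)
  floor_p <- 2 / n_draws
  rows <- lapply(seq_along(labels), function(j) {
    x <- draws[, j]
    hpd <- hpd_interval(x, prob)
    is_var <- j > p_fixed
    pm <- if (is_var) NA_real_ else max(floor_p, 2 * min(mean(x > 0), mean(x < 0)))
    data.frame(parameter = labels[j], post_mean = mean(x),
               lower = hpd[["lower"]], upper = hpd[["upper"]],
               pMCMC = pm,
               pMCMC_fmt = if (is_var) NA_character_
                           else if (pm <= floor_p) sprintf("< %.4g", ceiling(floor_p * 1e4) / 1e4)
                           else sprintf("%.4g", pm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
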