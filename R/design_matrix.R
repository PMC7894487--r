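#' Variable transforms used before standardization
#'
#' \code{log10p}: log10(x + 1), for area variables spanning orders of
#' magnitude; \code{sqrt}: square root, for right-skewed proportions and the
#' naturalization-success index; \code{identity}: no-op.
#'
#' @param values numeric vector.
#' @param method one of \code{"identity"}, \code{"log10p"}, \code{"sqrt"}.
#' @return transformed vector.
#' @export
transform_values <- function(values, method = c("identity", "log10p", "sqrt")) {
  method <- match.arg(method)
  if (method == "identity") return(values)
  neg <- which(values < 0)
  if (length(neg)) {
    stop(method, " requires non-negative input; offending rows: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  switch(method, log10p = log10(values + 1), sqrt = sqrt(values))
}

#' Standardize to mean 0, SD 1
#'
#' Sample SD (n - 1 denominator). Errors on constant input rather than
#' dividing by zero.
#'
#' @param values numeric vector with >= 2 distinct values.
#' @return standardized vector.
#' @export
standardize <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector", call. = FALSE)
  (values - mean(values)) / s
}

#' Model specifications for the three naturalization models
#'
#' \code{model1}: diversification rate + mean family range + horticultural
#' use. \code{model2}: diversification rate + tropical and temperate mean
#' ranges + horticultural use + (rate x tropical) + (rate x temperate).
#' \code{model3}: the model-2 main effects + (rate x horticultural use).
#' Diversification rate is present in every model by design.
#'
#' @param name one of \code{"model1"}, \code{"model2"}, \code{"model3"}.
#' @return a model spec list (\code{response}, \code{effects},
#'   \code{interactions}, \code{transforms}).
#' @export
model_spec <- function(name = c("model1", "model2", "model3")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    response = "nat_success",
    transforms = default_transforms()
  )
  specs <- list(
    model1 = list(effects = c("div_rate", "mean_range_km2", "hort_prop"),
                  interactions = list()),
    model2 = list(effects = c("div_rate", "mean_tropical_km2", "mean_temperate_km2", "hort_prop"),
                  interactions = list(c("div_rate", "mean_tropical_km2"),
                                      c("div_rate", "mean_temperate_km2"))),
    model3 = list(effects = c("div_rate", "mean_tropical_km2", "mean_temperate_km2", "hort_prop"),
                  interactions = list(c("div_rate", "hort_prop")))
  )
  c(base, specs[[name]])
}

#' Default transform map
#'
#' Areas are log10(x+1)-transformed (they span orders of magnitude),
#' proportions and the naturalization-success response square-root
#' transformed, the diversification rate left untouched.
#'
#' @return named character vector column -> method.
#' @export
default_transforms <- function() {
  c(div_rate = "identity",
    mean_range_km2 = "log10p",
    mean_tropical_km2 = "log10p",
    mean_temperate_km2 = "log10p",
    hort_prop = "sqrt",
    nat_success = "sqrt")
}

#' Build the response vector and design matrix for a model
#'
#' Main-effect columns are transformed (per the model spec's transform map), then
#' standardized to mean 0 / SD 1; interaction columns are elementwise
#' products of the standardized parents and are not re-standardized, so main
#' effects stay interpretable at the interaction's zero point. The response
#' is transformed but by default not standardized.
#'
#' @param data family dataset (one row per family).
#' @param spec model spec from \code{\link{model_spec}} or a custom list with
#'   the same fields.
#' @param standardize_response also standardize the transformed response
#'   (default FALSE).
#' @return list \code{y} (response), \code{X} (matrix with intercept first),
#'   \code{labels} (column names), \code{families}.
#' @export
build_design <- function(data, spec, standardize_response = FALSE) {
  need <- unique(c(spec$response, spec$effects, unlist(spec$interactions)))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("columns absent from data: ", paste(miss, collapse = ", "), call. = FALSE)
  for (ia in spec$interactions) {
    if (!all(ia %in% spec$effects)) {
      stop("interaction ", paste(ia, collapse = ":"),
           " references a non-main-effect column", call. = FALSE)
    }
  }
  if (anyNA(data[, need])) stop("missing values in model columns; drop those rows first", call. = FALSE)

  tmap <- spec$transforms
  get_method <- function(col) if (col %in% names(tmap)) tmap[[col]] else "identity"

  mains <- vapply(spec$effects, function(col) {
    standardize(transform_values(data[[col]], get_method(col)))
  }, numeric(nrow(data)))
  colnames(mains) <- spec$effects

  inters <- NULL
  if (length(spec$interactions)) {
    inters <- vapply(spec$interactions, function(ia) {
      mains[, ia[1]] * mains[, ia[2]]
    }, numeric(nrow(data)))
    colnames(inters) <- vapply(spec$interactions, paste, character(1), collapse = ":")
  }

  X <- cbind(`(Intercept)` = 1, mains, inters)
  y <- transform_values(data[[spec$response]], get_method(spec$response))
  if (standardize_response) y <- standardize(y)
  list(y = y, X = X, labels = colnames(X),
       families = if (!is.null(data$family)) data$family else rownames(data))
}

#' Pearson correlations among predictors
#'
#' Audit of predictor collinearity: pairwise Pearson correlations of the
#' design columns (intercept excluded) plus the off-diagonal entry of
#' largest absolute value.
#'
#' @param X design matrix without intercept (>= 3 rows).
#' @return list \code{correlations} (symmetric matrix), \code{strongest}
#'   (value), \code{strongest_pair} (column names).
#' @export
predictor_correlations <- function(X) {
  if (nrow(X) < 3L) stop("need >= 3 rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  C <- stats::cor(X)
  off <- C; diag(off) <- 0
  idx <- which(abs(off) == max(abs(off)), arr.ind = TRUE)[1, ]
  list(correlations = C,
       strongest = off[idx[1], idx[2]],
       strongest_pair = colnames(C)[c(idx[1], idx[2])])
}
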