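#' Spearman rank correlation of an ordinal trait with age
#'
#' Tie-corrected (midrank) Spearman rho with a large-sample t
#' approximation for the two-sided p-value. Pairs with a missing value in
#' either vector are dropped.
#'
#' @param stages ordinal stage vector.
#' @param ages numeric age vector, same length.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(stages, ages) {
  keep <- !is.na(stages) & !is.na(ages)
  x <- stages[keep]; y <- ages[keep]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .EPS))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Correlation ratio (eta squared) of age across trait stages
#'
#' Between-group sum of squares of age over the total sum of squares,
#' treating each observed stage as a group: the share of age variance
#' explained by the trait's stage grouping, in [0, 1].
#'
#' @inheritParams spearman_rho
#' @return A list with `eta_squared`, `n`.
#' @export
eta_squared <- function(stages, ages) {
  keep <- !is.na(stages) & !is.na(ages)
  x <- stages[keep]; y <- ages[keep]
  if (length(unique(x)) < 2L) stop("need at least 2 stage groups")
  sst <- sum((y - mean(y))^2)
  if (sst < .EPS) return(list(eta_squared = NA_real_, n = length(y)))
  group_means <- tapply(y, x, mean)
  group_n <- tapply(y, x, length)
  ssb <- sum(group_n * (group_means - mean(y))^2)
  list(eta_squared = ssb / sst, n = length(y))
}

# Schafer-Strimmer analytic shrinkage intensity toward the identity
# target, computed from the variance of the empirical correlations.
.shrinkage_intensity <- function(xs) {
  n <- nrow(xs); p <- ncol(xs)
  r <- stats::cor(xs)
  # var of each off-diagonal correlation via the w_ij products
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- xs[, i] * xs[, j]
      num <- num + n / ((n - 1)^3) * sum((w - mean(w))^2)
      den <- den + r[i, j]^2
    }
  }
  if (den < .EPS) return(1)
  min(1, max(0, num / den))
}

#' Sphere (Mahalanobis-transform) a standardized matrix
#'
#' Decorrelates the columns of a column-standardized matrix:
#' `Z = X %*% R^(-1/2)` where `R` is the (optionally shrunk) correlation
#' matrix and `R^(-1/2)` its symmetric inverse square root, so the
#' empirical covariance of `Z` is the identity. When `R` is
#' ill-conditioned (or `n <= p`), `R` is first shrunk toward the identity
#' with an analytically chosen intensity and a warning is issued.
#'
#' @param x numeric matrix with column mean 0 and variance 1.
#' @param shrink `NULL` (automatic: shrink only when needed), a numeric
#'   intensity in [0, 1], or `TRUE` to force the analytic intensity.
#' @return A list with `z` (sphered matrix), `w` (the `R^(-1/2)`
#'   transform), `lambda` (shrinkage intensity used, 0 if none).
#' @export
sphere <- function(x, shrink = NULL) {
  x <- as.matrix(x)
  if (max(abs(colMeans(x))) > 1e-6 || max(abs(.col_sds(x) - 1)) > 1e-6) {
    stop("x must be column-standardized (mean 0, variance 1)")
  }
  r <- stats::cor(x)
  lambda <- 0
  need_shrink <- nrow(x) <= ncol(x) ||
    kappa(r, exact = FALSE) > 1e8 ||
    isTRUE(shrink)
  if (is.numeric(shrink)) {
    lambda <- shrink
  } else if (need_shrink) {
    lambda <- .shrinkage_intensity(x)
    if (is.null(shrink)) {
      warning(sprintf(
        "correlation matrix ill-conditioned; shrinking toward identity (lambda = %.3f)",
        lambda))
    }
  }
  if (lambda > 0) r <- (1 - lambda) * r + lambda * diag(ncol(x))
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, .EPS)
  w <- e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  dimnames(w) <- list(colnames(x), colnames(x))
  list(z = x %*% w, w = w, lambda = lambda)
}

#' CAR scores: correlation-adjusted marginal correlations with age
#'
#' Marginal correlations of the predictors with the response computed
#' after sphering the predictors: `omega = R^(-1/2) %*% r_xy`, where
#' `r_xy` holds the marginal Pearson correlations of the standardized
#' traits with standardized age. Squared CAR scores decompose the
#' multiple R-squared of the full least-squares fit, so ranking traits by
#' squared CAR gives a fast, decorrelation-aware feature ranking.
#' Significance of each decorrelated correlation uses a t statistic with
#' n - 2 degrees of freedom.
#'
#' @param x trait matrix (complete; integer stage codes are used as
#'   numeric values and standardized internally) or `obs_matrix`.
#' @param y numeric response (ages).
#' @param shrink passed to [sphere()]; a singular correlation matrix
#'   falls back to the analytic shrinkage estimator automatically.
#' @return A data.frame with `trait_id`, `car`, `car_rank`,
#'   `p_value`, plus attribute `"lambda"` (shrinkage intensity).
#' @export
car_scores <- function(x, y, shrink = NULL) {
  x <- .stages(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("x must be complete; impute first")
  n <- nrow(x)
  xs <- .standardize(x, colMeans(x), .col_sds(x))
  ys <- (y - mean(y)) / stats::sd(y)
  sph <- sphere(xs, shrink = shrink)
  r_xy <- drop(stats::cor(xs, ys))
  omega <- drop(sph$w %*% r_xy)
  tstat <- omega * sqrt((n - 2) / pmax(1 - omega^2, .EPS))
  out <- data.frame(
    trait_id = colnames(x) %||% paste0("x", seq_along(omega)),
    car = omega,
    car_rank = rank(-omega^2, ties.method = "first"),
    p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
    stringsAsFactors = FALSE
  )
  attr(out, "lambda") <- sph$lambda
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full marginal + decorrelated feature report
#'
#' Combines Spearman rho, the correlation ratio eta-squared, and CAR
#' scores (with CAR-based ranking) for every trait, each with a
#' two-sided significance flag at the given level.
#'
#' @inheritParams car_scores
#' @param alpha significance level for the per-statistic flags.
#' @return A data.frame with one row per trait: `trait_id`, `rho`,
#'   `rho_significant`, `eta2`, `car`, `car_rank`, `car_significant`.
#' @export
#' @examples
#' sim <- simulate_skeletal(generator_config(n = 120, seed = 7))
#' obs <- impute_nn1_jaccard(sim$obs, sim$schema)
#' head(rank_features(obs, sim$obs$ages))
rank_features <- function(x, y, alpha = 0.05, shrink = NULL) {
  stages <- .stages(x)
  car <- car_scores(stages, y, shrink = shrink)
  rho <- vapply(seq_len(ncol(stages)), function(j) {
    unlist(spearman_rho(stages[, j], y)[c("rho", "p_value")])
  }, numeric(2))
  eta2 <- vapply(seq_len(ncol(stages)), function(j) {
    eta_squared(stages[, j], y)$eta_squared
  }, numeric(1))
  data.frame(
    trait_id = car$trait_id,
    rho = rho[1, ],
    rho_significant = rho[2, ] < alpha,
    eta2 = eta2,
    car = car$car,
    car_rank = car$car_rank,
    car_significant = car$p_value < alpha,
    stringsAsFactors = FALSE
  )
}
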