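#' Fit a global linear surrogate of the network
#'
#' Regresses the network's cross-validated (leave-one-out) predictions on
#' the sphered, standardized traits by ordinary least squares. Because
#' the sphered predictors are centered and orthogonal, the intercept is
#' exactly the mean of the network estimates (the "baseline"), and each
#' coefficient reads as years per standardized-sphered unit of one trait
#' — an additive, human-readable approximation of the network.
#'
#' @param model a fitted `drnn` (used for its stored training traits; its
#'   `loo_predictions` are the default target).
#' @param x the complete training trait matrix (or `obs_matrix`) the
#'   model was fitted on.
#' @param loo_predictions cross-validated predictions to explain;
#'   defaults to `model$loo_predictions`.
#' @param shrink passed to [sphere()]; rank deficiency after sphering
#'   falls back to the shrinkage estimator.
#' @return An object of class `drnn_surrogate`: coefficients (years per
#'   sphered unit), `intercept` (years), `r_squared`, `residual_sd`
#'   (years), and the frozen standardization + sphering transforms.
#' @export
#' @examples
#' sim <- simulate_skeletal(generator_config(n = 100, seed = 2))
#' obs <- impute_nn1_jaccard(sim$obs, sim$schema)
#' fit <- drnn_fit(obs, seed = 2)
#' sur <- fit_surrogate(fit, obs)
#' sur$r_squared
fit_surrogate <- function(model, x, loo_predictions = NULL, shrink = NULL) {
  stopifnot(inherits(model, "drnn"))
  x <- .stages(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("x must be complete; impute first")
  if (!is.null(colnames(x))) x <- x[, model$traits, drop = FALSE]
  if (is.null(loo_predictions)) loo_predictions <- model$loo_predictions
  if (length(loo_predictions) != nrow(x)) {
    stop("loo_predictions must align with the rows of x")
  }

  x_center <- colMeans(x)
  x_scale <- .col_sds(x)
  xs <- .standardize(x, x_center, x_scale)
  sph <- tryCatch(sphere(xs, shrink = shrink), error = function(e) {
    sphere(xs, shrink = TRUE)
  })
  z <- sph$z
  ls <- stats::lsfit(z, loo_predictions, intercept = TRUE)
  coefs <- ls$coefficients[-1L]
  names(coefs) <- colnames(x)
  res <- ls$residuals
  sst <- sum((loo_predictions - mean(loo_predictions))^2)
  structure(
    list(coefficients = coefs,
         intercept = unname(ls$coefficients[1L]),
         r_squared = 1 - sum(res^2) / sst,
         residual_sd = stats::sd(res),
         x_center = x_center, x_scale = x_scale,
         sphering = sph$w, lambda = sph$lambda,
         traits = colnames(x)),
    class = "drnn_surrogate"
  )
}

#' @export
print.drnn_surrogate <- function(x, ...) {
  cat(sprintf(
    "<drnn_surrogate> %d traits, R^2 = %.3f, baseline = %.1f years\n",
    length(x$coefficients), x$r_squared, x$intercept))
  invisible(x)
}

#' Explain one estimate as a sum of trait contributions
#'
#' Decomposes the surrogate approximation of a network estimate for a
#' single individual into additive per-trait contributions (years):
#' `contribution_k = coefficient_k * sphered standardized value_k`, so
#' `baseline + sum(contributions)` equals the surrogate approximation
#' exactly. Contributions are sorted by absolute magnitude. The
#' surrogate's residual SD bounds how far the approximation typically
#' sits from the true network estimate.
#'
#' @param surrogate a `drnn_surrogate`.
#' @param x_row a single complete trait row (named vector, 1-row matrix,
#'   or 1-row `obs_matrix`).
#' @return An object of class `case_explanation`: `contributions`
#'   (data.frame of trait_id, contribution, sorted by |contribution|),
#'   `baseline`, `approximation`, `residual_sd`, all in years.
#' @export
explain_case <- function(surrogate, x_row) {
  stopifnot(inherits(surrogate, "drnn_surrogate"))
  x <- .stages(x_row)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x_row)))
  storage.mode(x) <- "double"
  if (nrow(x) != 1L) stop("explain one individual at a time")
  if (anyNA(x)) stop("row has missing values; impute first")
  if (!is.null(colnames(x))) x <- x[, surrogate$traits, drop = FALSE]
  xs <- .standardize(x, surrogate$x_center, surrogate$x_scale)
  z <- drop(xs %*% surrogate$sphering)
  contrib <- surrogate$coefficients * z
  ord <- order(abs(contrib), decreasing = TRUE)
  structure(
    list(contributions = data.frame(trait_id = surrogate$traits[ord],
                                    contribution = unname(contrib[ord]),
                                    stringsAsFactors = FALSE),
         baseline = surrogate$intercept,
         approximation = surrogate$intercept + sum(contrib),
         residual_sd = surrogate$residual_sd),
    class = "case_explanation"
  )
}

#' @export
print.case_explanation <- function(x, ...) {
  cat(sprintf("baseline      %8.2f years\n", x$baseline))
  top <- utils::head(x$contributions, 8)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("%-12s  %+8.2f\n", top$trait_id[i], top$contribution[i]))
  }
  if (nrow(x$contributions) > 8) {
    rest <- sum(x$contributions$contribution[-seq_len(8)])
    cat(sprintf("%-12s  %+8.2f\n", "(others)", rest))
  }
  cat(sprintf("approximation %8.2f years (surrogate residual SD %.2f)\n",
              x$approximation, x$residual_sd))
  invisible(x)
}
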