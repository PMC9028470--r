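#' Fit a regression uncertainty model (RUM)
#'
#' Models the conditional spread of the age estimator by regressing the
#' absolute leave-one-out residuals `|y - loo|` on the leave-one-out
#' predictions themselves. The predicted absolute residual, scaled by
#' 1.2533 (the Gaussian SD-to-mean-absolute-deviation ratio, sqrt(pi/2)
#' to four decimals), gives a conditional standard deviation for each
#' point estimate; prediction intervals then come from a Gaussian — by
#' default truncated below at the minimum training age, since an adult
#' skeletal sample carries no information below its youngest individual.
#'
#' @param loo_predictions cross-validated (leave-one-out) point estimates
#'   from the age model, in years.
#' @param y known ages, paired with `loo_predictions` (length >= 10).
#' @param engine residual regressor: `"drnn"` (default; a depth-1
#'   randomized network on the single predictor, ridge-tuned by PRESS) or
#'   `"linear"` (simple least squares).
#' @param floor_sd floor on the predicted absolute residual, in years,
#'   preventing zero-width intervals (default 1).
#' @param lower,upper truncation bounds in years for the interval
#'   distribution. Defaults: `min(y)` and `Inf`.
#' @param seed seed for the randomized-network engine.
#' @return An object of class `rum`.
#' @export
#' @examples
#' set.seed(1)
#' loo <- runif(200, 20, 90)
#' y <- loo + rnorm(200, 0, 6)
#' rum <- fit_rum(loo, y, engine = "linear")
#' rum_interval(rum, point = 55, alpha = 0.05)
fit_rum <- function(loo_predictions, y,
                    engine = c("drnn", "linear"),
                    floor_sd = 1, lower = min(y), upper = Inf,
                    seed = 1L) {
  engine <- match.arg(engine)
  if (length(loo_predictions) != length(y)) {
    stop("loo_predictions and y must be paired")
  }
  if (length(y) < 10L) stop("need at least 10 training pairs")
  if (lower >= upper) stop("lower truncation bound must be below upper")
  abs_res <- abs(y - loo_predictions)

  degenerate <- all(abs_res < .EPS)
  model <- NULL
  if (degenerate) {
    warning("all residuals are zero; uncertainty model degenerates to the floor")
    engine <- "constant"
  } else if (engine == "linear") {
    model <- stats::lm(abs_res ~ loo_predictions,
                       data = data.frame(abs_res = abs_res,
                                         loo_predictions = loo_predictions))
  } else {
    model <- drnn_fit(matrix(loo_predictions, ncol = 1,
                             dimnames = list(NULL, "point")),
                      abs_res, seed = seed, depth = 1L)
  }
  structure(
    list(engine = engine, model = model,
         scale_constant = 1.2533,
         floor_sd = floor_sd, lower = lower, upper = upper,
         age_range = range(y)),
    class = "rum"
  )
}

#' @export
print.rum <- function(x, ...) {
  cat(sprintf("<rum> engine = %s, truncation [%.1f, %s] years\n",
              x$engine, x$lower,
              if (is.finite(x$upper)) sprintf("%.1f", x$upper) else "Inf"))
  invisible(x)
}

#' Conditional standard deviation from a RUM
#'
#' `sd = 1.2533 * max(predicted absolute residual, floor)`.
#'
#' @param model a fitted `rum`.
#' @param point point estimate(s), years.
#' @return Numeric vector of standard deviations, years (always > 0).
#' @export
predict_sd <- function(model, point) {
  stopifnot(inherits(model, "rum"))
  pred <- switch(model$engine,
    constant = rep(0, length(point)),
    linear = unname(stats::predict(model$model,
                                   data.frame(loo_predictions = point))),
    drnn = predict(model$model,
                   matrix(point, ncol = 1, dimnames = list(NULL, "point")))
  )
  model$scale_constant * pmax(pred, model$floor_sd)
}

# quantile of a Gaussian(mu, sd) truncated to [a, b]
.qtruncnorm <- function(p, mu, sd, a, b) {
  fa <- stats::pnorm(a, mu, sd)
  fb <- stats::pnorm(b, mu, sd)
  stats::qnorm(fa + p * (fb - fa), mu, sd)
}

#' Prediction interval from a RUM
#'
#' Central `1 - alpha` interval of a Gaussian centred at the point
#' estimate with the RUM's conditional standard deviation, truncated to
#' the model's bounds (untruncated when the bounds are infinite). A point
#' far outside the truncation bounds (vanishing truncated mass) yields
#' the widest valid interval with a warning.
#'
#' @param model a fitted `rum`.
#' @param point point estimate(s), years.
#' @param alpha uncertainty level in (0, 1); 0.05 gives a 95% interval.
#' @return data.frame with `point`, `sd`, `lower`, `upper`, `alpha`.
#' @export
rum_interval <- function(model, point, alpha = 0.05) {
  stopifnot(inherits(model, "rum"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  sd <- predict_sd(model, point)
  lo <- hi <- numeric(length(point))
  for (i in seq_along(point)) {
    mass <- stats::pnorm(model$upper, point[i], sd[i]) -
      stats::pnorm(model$lower, point[i], sd[i])
    if (mass < 1e-10) {
      warning("point estimate lies far outside the truncation bounds; ",
              "returning the widest valid interval")
      lo[i] <- if (is.finite(model$lower)) model$lower else
        point[i] - 10 * sd[i]
      hi[i] <- if (is.finite(model$upper)) model$upper else
        max(model$age_range[2], model$lower, point[i]) + 10 * sd[i]
    } else {
      lo[i] <- .qtruncnorm(alpha / 2, point[i], sd[i], model$lower, model$upper)
      hi[i] <- .qtruncnorm(1 - alpha / 2, point[i], sd[i], model$lower,
                           model$upper)
    }
  }
  data.frame(point = point, sd = sd, lower = lo, upper = hi, alpha = alpha)
}
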