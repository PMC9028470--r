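#' Mean absolute error
#'
#' @param y known values; @param y_hat predictions, same length.
#' @return Mean of `|y - y_hat|`, in the units of `y` (years).
#' @export
mae <- function(y, y_hat) {
  if (length(y) != length(y_hat) || !length(y)) {
    stop("y and y_hat must be nonempty and the same length")
  }
  mean(abs(y - y_hat))
}

#' Prediction bias slope
#'
#' Slope of the simple regression of the residuals `e_i = y_i - y_hat_i`
#' on the known values `y_i`. Near zero for an unbiased model; a positive
#' slope is the classic age-estimation pathology (over-estimating the
#' young, under-estimating the elderly). A mean-only predictor scores
#' exactly 1.
#'
#' @inheritParams mae
#' @return The slope (dimensionless).
#' @export
bias_slope <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 3L) {
    stop("need at least 3 paired values")
  }
  if (stats::var(y) < .EPS) stop("y is constant; slope undefined")
  e <- y - y_hat
  sum((y - mean(y)) * (e - mean(e))) / sum((y - mean(y))^2)
}

#' Empirical interval coverage
#'
#' Fraction of known values inside their closed prediction intervals.
#'
#' @param y known values.
#' @param lower,upper interval bounds, aligned with `y`.
#' @return Proportion in [0, 1].
#' @export
coverage <- function(y, lower, upper) {
  if (length(y) != length(lower) || length(y) != length(upper)) {
    stop("y, lower, upper must be aligned")
  }
  if (any(lower > upper)) stop("every interval needs lower <= upper")
  mean(y >= lower & y <= upper)
}

#' Prediction-interval width quantiles
#'
#' Quantiles of the interval widths `upper - lower` — the efficiency of
#' an interval-producing model (narrow intervals at valid coverage).
#' Quantiles interpolate linearly between order statistics
#' (`quantile(type = 7)`).
#'
#' @inheritParams coverage
#' @param taus quantile levels; default the median with a quantile-based
#'   95% band.
#' @return Named numeric vector of width quantiles (years).
#' @export
piw <- function(lower, upper, taus = c(0.5, 0.025, 0.975)) {
  if (!length(lower)) stop("empty input")
  if (length(lower) != length(upper)) stop("lower and upper must be aligned")
  if (any(lower > upper)) stop("every interval needs lower <= upper")
  stats::quantile(upper - lower, probs = taus, type = 7)
}

# one MCCV iteration's metrics
.mccv_metrics <- function(y, y_hat, intervals) {
  w <- piw(intervals$lower, intervals$upper)
  c(mae = mae(y, y_hat),
    bias = bias_slope(y, y_hat),
    coverage = coverage(y, intervals$lower, intervals$upper),
    piw_50 = unname(w[1]), piw_025 = unname(w[2]), piw_975 = unname(w[3]))
}

#' Monte Carlo cross-validation of the full estimation pipeline
#'
#' Repeats `B` times: draw disjoint train/test partitions without
#' replacement (default 80/20), optionally restrict to a named trait
#' preset or a random subset of traits at a configured fraction (the
#' available-traits experiment), impute missing stages, fit the deep
#' randomized network and its uncertainty model on the training
#' partition, predict the test partition with prediction intervals, and
#' score accuracy (MAE), bias slope, coverage, and interval-width
#' quantiles. Aggregates report the median and the 2.5%/97.5% quantiles
#' of each metric across iterations. Fully reproducible from `seed`.
#'
#' By default imputation is leakage-safe: training rows are imputed among
#' themselves and test rows draw donors from the training partition only.
#' `global_impute = TRUE` instead imputes the full dataset once up front,
#' reproducing the order of operations of a global-imputation design.
#'
#' @param obs an `obs_matrix` with ages (missing stages allowed).
#' @param schema a `trait_schema` covering the data.
#' @param B number of Monte Carlo iterations.
#' @param train_fraction fraction of individuals in the training
#'   partition (default 0.8).
#' @param alpha interval uncertainty level (default 0.05).
#' @param seed master seed for partitions, trait draws, and network
#'   weights.
#' @param traits optional preset name or trait-id vector (see
#'   [resolve_preset()]).
#' @param trait_fraction optional fraction in (0, 1]; each iteration uses
#'   a fresh random subset of this share of the traits.
#' @param global_impute impute once on the full data instead of within
#'   partitions.
#' @param engine uncertainty-model engine, see [fit_rum()].
#' @return An object of class `mccv_report`: list with `iterations`
#'   (B-row data.frame of per-iteration metrics), `summary` (median and
#'   2.5/97.5% quantiles per metric), and `config`.
#' @export
#' @examples
#' sim <- simulate_skeletal(generator_config(n = 120, seed = 3))
#' rep <- mccv(sim$obs, sim$schema, B = 2, seed = 3)
#' rep$summary
mccv <- function(obs, schema, B = 50, train_fraction = 0.8, alpha = 0.05,
                 seed = 1L, traits = NULL, trait_fraction = NULL,
                 global_impute = FALSE, engine = c("drnn", "linear")) {
  stopifnot(inherits(obs, "obs_matrix"), inherits(schema, "trait_schema"))
  engine <- match.arg(engine)
  if (is.null(obs$ages)) stop("obs must carry known ages")
  if (B < 1L) stop("B must be at least 1")
  n <- nrow(obs$stages)
  n_train <- as.integer(round(n * train_fraction))
  if (n_train < 4L) stop("training partition smaller than the heuristic minimum (4)")
  if (n_train >= n) stop("train_fraction leaves no test partition")

  stages <- obs$stages
  if (!is.null(traits)) {
    keep <- resolve_preset(traits, schema)
    stages <- stages[, keep, drop = FALSE]
  }
  pool <- colnames(stages)
  sub_schema <- trait_schema(schema[match(pool, schema$trait_id), ,
                                    drop = FALSE])

  if (global_impute && anyNA(stages)) {
    stages <- impute_nn1_jaccard(
      observation_matrix(stages, schema = sub_schema), sub_schema)$stages
  }

  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, B)

  rows <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(iter_seeds[b])
    idx_train <- sample.int(n, n_train)
    idx_test <- setdiff(seq_len(n), idx_train)

    cols <- pool
    if (!is.null(trait_fraction)) {
      m_sub <- max(1L, round(length(pool) * trait_fraction))
      cols <- sample(pool, m_sub)
    }
    it_schema <- trait_schema(sub_schema[match(cols, sub_schema$trait_id), ,
                                         drop = FALSE])
    tr <- observation_matrix(stages[idx_train, cols, drop = FALSE],
                             ages = obs$ages[idx_train], schema = it_schema)
    te <- observation_matrix(stages[idx_test, cols, drop = FALSE],
                             ages = obs$ages[idx_test], schema = it_schema)
    if (anyNA(tr$stages)) tr <- impute_nn1_jaccard(tr, it_schema)
    if (anyNA(te$stages)) te <- impute_nn1_jaccard(te, it_schema, donors = tr)

    fit <- drnn_fit(tr, seed = iter_seeds[b])
    rum <- fit_rum(fit$loo_predictions, tr$ages, engine = engine,
                   seed = iter_seeds[b])
    pt <- predict(fit, te)
    iv <- rum_interval(rum, pt, alpha = alpha)
    rows[[b]] <- .mccv_metrics(te$ages, pt, iv)
  }

  iterations <- as.data.frame(do.call(rbind, rows))
  iterations <- cbind(iteration = seq_len(B), iterations)
  metrics <- setdiff(names(iterations), "iteration")
  summary <- data.frame(
    metric = metrics,
    median = vapply(metrics, function(m)
      stats::median(iterations[[m]]), numeric(1)),
    ci_low = vapply(metrics, function(m)
      unname(stats::quantile(iterations[[m]], 0.025, type = 7)), numeric(1)),
    ci_high = vapply(metrics, function(m)
      unname(stats::quantile(iterations[[m]], 0.975, type = 7)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(iterations = iterations, summary = summary,
         config = list(B = B, n = n, n_train = n_train,
                       n_test = n - n_train, alpha = alpha, seed = seed,
                       traits = pool, trait_fraction = trait_fraction,
                       global_impute = global_impute, engine = engine)),
    class = "mccv_report"
  )
}

#' @export
print.mccv_report <- function(x, ...) {
  cat(sprintf("<mccv_report> B = %d, train/test = %d/%d, alpha = %.2f\n",
              x$config$B, x$config$n_train, x$config$n_test, x$config$alpha))
  print(x$summary, digits = 4)
  invisible(x)
}
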