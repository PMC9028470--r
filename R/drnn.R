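#' Architecture-sizing heuristic for deep randomized networks
#'
#' Sizes a deep randomized network from the training-set size alone:
#' with `k = log2(n)`, the total number of randomized units is
#' `S = 2^floor(log2(8 * (2^k / k)))` and the depth is
#' `L = 2^floor(log2(k))`, giving a rectangular topology of `L` layers of
#' `S / L` units each. For n = 500 this yields 8 layers of 32 units
#' (256 randomized units in total) — enough random feature extractors
#' spread over depth without over-parameterizing the analytic output
#' layers.
#'
#' @param n training-set size (must be at least 4 so that `k >= 2`).
#' @return An object of class `drnn_architecture`: list with `n`, `k`,
#'   `total_units`, `depth`, `width`.
#' @export
#' @examples
#' architecture_heuristic(500)  # depth 8, width 32, 256 units
architecture_heuristic <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 4) {
    stop("architecture heuristic requires n >= 4")
  }
  k <- log2(n)
  total <- 2^floor(log2(8 * (2^k / k)))
  depth <- 2^floor(log2(k))
  structure(
    list(n = as.integer(n), k = k,
         total_units = as.integer(total),
         depth = as.integer(depth),
         width = as.integer(total / depth)),
    class = "drnn_architecture"
  )
}

#' @export
print.drnn_architecture <- function(x, ...) {
  cat(sprintf("<drnn_architecture> n = %d: %d layers x %d units (%d total)\n",
              x$n, x$depth, x$width, x$total_units))
  invisible(x)
}

#' Initialize random hidden layers
#'
#' Draws the fixed (never-trained) hidden-layer weights. Layer 1 maps the
#' `n_inputs` traits to `width` units; every deeper layer maps the
#' previous layer's activations concatenated with the raw input (skip
#' connection) to `width` units. Each weight matrix carries a trailing
#' bias row. Fully reproducible from `seed`.
#'
#' @param arch a `drnn_architecture`.
#' @param n_inputs number of input columns.
#' @param seed integer RNG seed.
#' @param distribution `"gaussian"` (standard normal) or `"uniform"`
#'   (uniform on \[-1, 1\]).
#' @return List of `depth` weight matrices, each `(d_in + 1) x width`.
#' @export
init_layers <- function(arch, n_inputs, seed,
                        distribution = c("gaussian", "uniform")) {
  distribution <- match.arg(distribution)
  stopifnot(inherits(arch, "drnn_architecture"))
  draw <- switch(distribution,
                 gaussian = function(k) stats::rnorm(k),
                 uniform = function(k) stats::runif(k, -1, 1))
  set.seed(seed)
  lapply(seq_len(arch$depth), function(j) {
    d_in <- if (j == 1L) n_inputs else arch$width + n_inputs
    matrix(draw((d_in + 1L) * arch$width), d_in + 1L, arch$width)
  })
}

# Forward pass. In training mode (scalers = NULL) the per-unit
# standardization statistics of pre-activations and activations are
# computed and returned; in prediction mode the stored statistics are
# reused so the feature map is frozen at its training form.
.drnn_forward <- function(weights, xs, scalers = NULL,
                          standardize_pre = TRUE, standardize_post = TRUE) {
  L <- length(weights)
  training <- is.null(scalers)
  if (training) scalers <- vector("list", L)
  hs <- vector("list", L)
  h_prev <- NULL
  for (j in seq_len(L)) {
    input <- if (j == 1L) xs else cbind(h_prev, xs)
    z <- cbind(input, 1) %*% weights[[j]]
    if (training) {
      sc <- list(
        pre_center = if (standardize_pre) colMeans(z) else NULL,
        pre_scale = if (standardize_pre) .col_sds(z) else NULL
      )
    } else sc <- scalers[[j]]
    if (standardize_pre) z <- .standardize(z, sc$pre_center, sc$pre_scale)
    a <- pmax(z, 0)
    if (training) {
      sc$post_center <- if (standardize_post) colMeans(a) else NULL
      sc$post_scale <- if (standardize_post) .col_sds(a) else NULL
      scalers[[j]] <- sc
    }
    if (standardize_post) a <- .standardize(a, sc$post_center, sc$post_scale)
    hs[[j]] <- a
    h_prev <- a
  }
  list(h = hs, scalers = scalers)
}

# Per-depth design matrix D(j) = [H(1) ... H(j) X].
.design <- function(hs, xs, depth) {
  cbind(do.call(cbind, hs[seq_len(depth)]), xs)
}

# economy SVD, isolated so tests can count invocations
.svd_econ <- function(x) svd(x)

#' Ridge regression via SVD with analytic leverages
#'
#' Solves the L2-penalized least squares problem with penalty `I / C`
#' (larger `C` = weaker regularization) through a thin SVD of the
#' centered design: with `D = U S V'`, the coefficients are
#' `beta = V diag(s / (s^2 + 1/C)) U' y` and the fitted values
#' `U diag(phi) U' y` with shrinkage factors `phi_i = s_i^2 / (s_i^2 +
#' 1/C)`. The leverage diagonal `h_ii = sum_k phi_k U_ik^2` comes free
#' from the same factorization and drives the analytic leave-one-out
#' error ([loo_press()]).
#'
#' Columns of `D` and `y` are centered internally (the intercept is not
#' penalized); pass pre-standardized columns if scale equivariance
#' matters, as [drnn_fit()] does.
#'
#' @param d design matrix.
#' @param y numeric target.
#' @param c_value ridge parameter `C > 0`.
#' @param factors optional precomputed list from a previous solve on the
#'   same `d` (fields `u`, `s`, `v`, `uty`, `x_center`, `y_center`);
#'   reused so a grid of `C` values costs a single SVD.
#' @return An object of class `ridge_fit`: `beta`, `intercept`, `c_value`,
#'   `fitted`, `h` (leverages), `phi`, `edf` (sum of `phi`),
#'   `loo_predictions`, `e_loo`, and `factors` for reuse.
#' @export
ridge_solve_svd <- function(d, y, c_value, factors = NULL) {
  if (c_value <= 0) stop("C must be positive")
  if (is.null(factors)) {
    d <- as.matrix(d)
    if (!all(is.finite(d)) || !all(is.finite(y))) {
      stop("design matrix and target must be finite")
    }
    x_center <- colMeans(d)
    y_center <- mean(y)
    dc <- sweep(d, 2L, x_center, `-`)
    sv <- .svd_econ(dc)
    keep <- sv$d > max(sv$d[1], 1) * .EPS
    factors <- list(u = sv$u[, keep, drop = FALSE], s = sv$d[keep],
                    v = sv$v[, keep, drop = FALSE],
                    uty = crossprod(sv$u[, keep, drop = FALSE], y - y_center),
                    x_center = x_center, y_center = y_center, n = nrow(d))
  }
  phi <- factors$s^2 / (factors$s^2 + 1 / c_value)
  beta <- drop(factors$v %*% ((factors$s / (factors$s^2 + 1 / c_value)) *
                                factors$uty))
  fitted_c <- drop(factors$u %*% (phi * factors$uty))
  h <- drop(factors$u^2 %*% phi)
  fit <- structure(
    list(beta = beta,
         intercept = factors$y_center - sum(factors$x_center * beta),
         c_value = c_value,
         fitted = fitted_c + factors$y_center,
         h = h, phi = phi, edf = sum(phi),
         factors = factors),
    class = "ridge_fit"
  )
  loo <- loo_press(fit, y)
  fit$loo_predictions <- loo$loo_predictions
  fit$e_loo <- loo$e_loo
  fit
}

#' Analytic leave-one-out (PRESS) predictions
#'
#' Computes exact leave-one-out residuals for a ridge solution without
#' refitting, via the PRESS identity: `r_i = (y_i - fitted_i) / (1 -
#' h_ii)`, `loo_i = y_i - r_i`, `E_LOO = mean(r_i^2)`. Valid whenever all
#' leverages are strictly below 1 (always true for a penalized solve on
#' the centered design; an `h_ii >= 1` indicates interpolation and raises
#' an error).
#'
#' @param fit a `ridge_fit`.
#' @param y the training target the fit was computed on.
#' @return A list with `e_loo` and `loo_predictions`.
#' @export
loo_press <- function(fit, y) {
  if (any(fit$h >= 1)) {
    stop("leverage h_ii >= 1: model interpolates; decrease C")
  }
  r <- (y - fit$fitted) / (1 - fit$h)
  list(e_loo = mean(r^2), loo_predictions = y - r)
}

#' Optimize the ridge parameter on a grid by leave-one-out error
#'
#' Evaluates the analytic PRESS leave-one-out error over a grid of `C`
#' values and returns the minimizer. The SVD of the design is computed
#' once and reused across the grid: only the shrinkage factors `phi`
#' change with `C`.
#'
#' @inheritParams ridge_solve_svd
#' @param grid numeric vector of candidate `C` values; default
#'   `2^seq(-6, 12, by = 2)`.
#' @return A list with `c_value` (the selected `C`), `fit` (its
#'   `ridge_fit`), and `path` (data.frame of `c_value`, `e_loo`).
#' @export
optimize_c <- function(d, y, grid = 2^seq(-6, 12, by = 2)) {
  if (!length(grid)) stop("grid must be nonempty")
  best <- NULL
  factors <- NULL
  path <- data.frame(c_value = grid, e_loo = NA_real_)
  for (i in seq_along(grid)) {
    fit <- ridge_solve_svd(d, y, grid[i], factors = factors)
    factors <- fit$factors
    if (any(fit$h >= 1)) next
    path$e_loo[i] <- fit$e_loo
    if (is.null(best) || fit$e_loo < best$e_loo) best <- fit
  }
  if (is.null(best)) stop("every grid value yields h_ii >= 1")
  list(c_value = best$c_value, fit = best, path = path)
}

#' Fit a deep randomized neural network regressor
#'
#' Trains the age-at-death regressor: input traits are standardized and
#' pushed through `depth` fixed random ReLU layers with skip connections
#' (every layer sees the previous layer's activations concatenated with
#' the raw standardized input). For each depth `j`, an independent ridge
#' output layer is solved analytically on the design `D(j) = [H(1) ...
#' H(j) X]`, with its own `C` selected on a grid by the exact SVD/PRESS
#' leave-one-out error. Predictions are the average of the per-depth
#' estimates, so the network is an implicit ensemble over depth. Hidden
#' weights are never trained; only the output layers are solved, making
#' fitting a handful of SVDs.
#'
#' Pre-activations and activations are standardized per unit using
#' training statistics (frozen for prediction), as the ridge penalty is
#' not scale invariant.
#'
#' @param x complete trait matrix (or complete `obs_matrix`): individuals
#'   x traits, integer stage codes used as numeric inputs.
#' @param y numeric ages-at-death (years). If `x` is an `obs_matrix`
#'   carrying ages, `y` may be omitted.
#' @param seed integer seed controlling the random layer weights.
#' @param depth,width optional overrides of the architecture heuristic;
#'   `depth = 1` gives a shallow random-layer network with skip
#'   connections (an RVFL network).
#' @param c_grid grid of ridge `C` candidates (default `2^x`,
#'   `x = -6, -4, ..., 12`).
#' @param distribution random weight distribution, see [init_layers()].
#' @param standardize_pre,standardize_post per-unit standardization
#'   toggles for pre-activations and activations.
#' @return An object of class `drnn`: the fitted model, including
#'   per-depth ridge solutions, frozen scalers, cross-validated
#'   (leave-one-out) predictions in years (`loo_predictions`), fitted
#'   ensemble values (`fitted`), and the training age range.
#' @export
#' @examples
#' sim <- simulate_skeletal(generator_config(n = 80, seed = 1))
#' obs <- impute_nn1_jaccard(sim$obs, sim$schema)
#' fit <- drnn_fit(obs, seed = 1)
#' head(fit$loo_predictions)
drnn_fit <- function(x, y = NULL, seed = 1L, depth = NULL, width = NULL,
                     c_grid = 2^seq(-6, 12, by = 2),
                     distribution = c("gaussian", "uniform"),
                     standardize_pre = TRUE, standardize_post = TRUE) {
  distribution <- match.arg(distribution)
  if (inherits(x, "obs_matrix") && is.null(y)) y <- x$ages
  x <- .stages(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("x must be complete; impute first")
  if (is.null(y)) stop("ages y are required")
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 training rows")
  if (length(y) != n) stop("y must have one value per row of x")
  if (stats::sd(y) < .EPS) stop("y is constant; nothing to regress")

  arch <- architecture_heuristic(n)
  if (!is.null(depth)) {
    w <- if (!is.null(width)) width else max(1L, arch$total_units %/% depth)
    arch <- structure(list(n = n, k = arch$k,
                           total_units = as.integer(depth * w),
                           depth = as.integer(depth), width = as.integer(w)),
                      class = "drnn_architecture")
  }
  # Analytic PRESS degenerates once a centered design can (near-)
  # interpolate: with >= n - 1 columns the rows of the centered design sum
  # to zero, every left-out row is a combination of the rest, and the LOO
  # error collapses to zero regardless of generalization. Cap the deepest
  # design strictly below that regime (never binding at the heuristic's
  # intended scale, e.g. n = 500 with 64 traits).
  budget <- (n - 2L) - ncol(x)
  if (budget >= 1L && arch$depth * arch$width > budget) {
    width_eff <- min(arch$width, budget)
    depth_eff <- max(1L, min(arch$depth, budget %/% width_eff))
    arch <- structure(list(n = n, k = arch$k,
                           total_units = as.integer(depth_eff * width_eff),
                           depth = as.integer(depth_eff),
                           width = as.integer(width_eff)),
                      class = "drnn_architecture")
  }

  x_center <- colMeans(x)
  x_scale <- .col_sds(x)
  xs <- .standardize(x, x_center, x_scale)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale

  weights <- init_layers(arch, ncol(x), seed, distribution)
  fwd <- .drnn_forward(weights, xs, NULL, standardize_pre, standardize_post)

  d_full <- .design(fwd$h, xs, arch$depth)
  d_center <- colMeans(d_full)
  d_scale <- .col_sds(d_full)
  d_std <- .standardize(d_full, d_center, d_scale)
  x_cols <- ncol(d_full) - ncol(x) + seq_len(ncol(x))

  solutions <- vector("list", arch$depth)
  loo_std <- matrix(NA_real_, n, arch$depth)
  fitted_std <- matrix(NA_real_, n, arch$depth)
  for (j in seq_len(arch$depth)) {
    cols <- c(seq_len(j * arch$width), x_cols)
    opt <- optimize_c(d_std[, cols, drop = FALSE], ys, c_grid)
    sol <- opt$fit
    sol$factors <- NULL  # drop training factorization; not needed to predict
    solutions[[j]] <- list(beta = sol$beta, intercept = sol$intercept,
                           c_value = sol$c_value, e_loo = sol$e_loo,
                           edf = sol$edf, cols = cols)
    loo_std[, j] <- opt$fit$loo_predictions
    fitted_std[, j] <- opt$fit$fitted
  }

  structure(
    list(architecture = arch, weights = weights, scalers = fwd$scalers,
         solutions = solutions,
         traits = colnames(x),
         x_center = x_center, x_scale = x_scale,
         d_center = d_center, d_scale = d_scale,
         y_center = y_center, y_scale = y_scale,
         loo_predictions = rowMeans(loo_std) * y_scale + y_center,
         fitted = rowMeans(fitted_std) * y_scale + y_center,
         loo_mae = mean(abs(y - (rowMeans(loo_std) * y_scale + y_center))),
         age_range = range(y),
         seed = seed, distribution = distribution,
         standardize_pre = standardize_pre,
         standardize_post = standardize_post),
    class = "drnn"
  )
}

#' @export
print.drnn <- function(x, ...) {
  cat(sprintf(
    "<drnn> %d traits, %d layers x %d units; LOO MAE %.2f years\n",
    length(x$traits), x$architecture$depth, x$architecture$width,
    x$loo_mae))
  invisible(x)
}

#' Predict age-at-death with a fitted deep randomized network
#'
#' Pushes new trait rows through the frozen random feature map and
#' averages the per-depth ridge estimates (the implicit depth ensemble).
#'
#' @param object a fitted `drnn`.
#' @param newdata complete trait matrix or `obs_matrix` with the training
#'   traits (any column order if named).
#' @param schema optional `trait_schema`; when supplied, stage codes are
#'   validated before prediction.
#' @param ... unused.
#' @return Numeric vector of point estimates in years.
#' @export
predict.drnn <- function(object, newdata, schema = NULL, ...) {
  x <- .stages(newdata)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("newdata must be complete; impute first")
  if (!is.null(colnames(x)) && !is.null(object$traits)) {
    missing_tr <- setdiff(object$traits, colnames(x))
    if (length(missing_tr)) {
      stop("newdata lacks trait(s): ", paste(missing_tr, collapse = ", "))
    }
    x <- x[, object$traits, drop = FALSE]
  } else if (ncol(x) != length(object$traits)) {
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(object$traits))
  }
  if (!is.null(schema)) validate_stages(x, schema)

  xs <- .standardize(x, object$x_center, object$x_scale)
  fwd <- .drnn_forward(object$weights, xs, object$scalers,
                       object$standardize_pre, object$standardize_post)
  d_full <- .design(fwd$h, xs, object$architecture$depth)
  d_std <- .standardize(d_full, object$d_center, object$d_scale)
  est <- vapply(object$solutions, function(sol) {
    drop(d_std[, sol$cols, drop = FALSE] %*% sol$beta) + sol$intercept
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) est <- matrix(est, nrow = 1L)
  unname(rowMeans(est) * object$y_scale + object$y_center)
}
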