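test_that("architecture heuristic reproduces its defining instantiations", {
  a500 <- architecture_heuristic(500)
  expect_identical(a500$depth, 8L)
  expect_identical(a500$width, 32L)
  expect_identical(a500$total_units, 256L)

  a4 <- architecture_heuristic(4)
  expect_identical(c(a4$total_units, a4$depth, a4$width), c(16L, 2L, 8L))

  a256 <- architecture_heuristic(256)
  expect_identical(c(a256$total_units, a256$depth, a256$width),
                   c(256L, 8L, 32L))

  expect_error(architecture_heuristic(3), "n >= 4")
})

test_that("random layers are reproducible and correctly shaped", {
  arch <- architecture_heuristic(500)
  w1 <- init_layers(arch, 64, seed = 7)
  w2 <- init_layers(arch, 64, seed = 7)
  expect_identical(w1, w2)
  expect_identical(dim(w1[[1]]), c(65L, 32L))       # 64 inputs + bias
  expect_identical(dim(w1[[3]]), c(97L, 32L))       # 32 + 64 skip + bias
  expect_identical(length(w1), 8L)
  w3 <- init_layers(arch, 64, seed = 8)
  expect_false(identical(w1[[1]], w3[[1]]))
})

test_that("ridge SVD solution equals the dense closed form", {
  set.seed(30)
  d <- matrix(rnorm(30 * 5), 30, 5)
  d <- sweep(d, 2, colMeans(d))           # pre-centered
  y <- rnorm(30)
  y <- y - mean(y)
  for (c_value in c(0.25, 4, 2^12)) {
    fit <- ridge_solve_svd(d, y, c_value)
    beta_dense <- solve(crossprod(d) + diag(5) / c_value, crossprod(d, y))
    expect_equal(fit$beta, drop(beta_dense), tolerance = 1e-8)
    # trace identity: sum of leverages equals sum of shrinkage factors
    expect_equal(sum(fit$h), sum(fit$phi), tolerance = 1e-10)
    expect_true(all(fit$h >= 0 & fit$h < 1))
  }
  # near-OLS at very large C on a well-conditioned design
  fit <- ridge_solve_svd(d, y, 2^20)
  expect_equal(fit$beta, drop(solve(crossprod(d), crossprod(d, y))),
               tolerance = 1e-4)
})

test_that("analytic PRESS equals explicit leave-one-out refits", {
  set.seed(31)
  d <- matrix(rnorm(20 * 4), 20, 4)
  y <- rnorm(20, sd = 2)
  dc <- sweep(d, 2, colMeans(d))
  yc <- y - mean(y)
  for (c_value in c(1, 64)) {
    fit <- ridge_solve_svd(dc, yc, c_value)
    explicit <- vapply(seq_len(20), function(i) {
      b <- solve(crossprod(dc[-i, ]) + diag(4) / c_value,
                 crossprod(dc[-i, ], yc[-i]))
      drop(dc[i, ] %*% b)
    }, numeric(1))
    expect_equal(fit$loo_predictions, explicit, tolerance = 1e-8)
    expect_equal(fit$e_loo, mean((yc - explicit)^2), tolerance = 1e-8)
  }
})

test_that("LOO error is never below the training error", {
  for (seed in 1:4) {
    set.seed(seed)
    d <- matrix(rnorm(25 * 6), 25, 6)
    y <- rnorm(25)
    fit <- ridge_solve_svd(d, y, 2)
    expect_gte(fit$e_loo, mean((y - fit$fitted)^2))
  }
})

test_that("effective degrees of freedom increase with C", {
  set.seed(33)
  d <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  edf <- vapply(2^seq(-6, 12, 2), function(c_value) {
    ridge_solve_svd(d, y, c_value)$edf
  }, numeric(1))
  expect_true(all(diff(edf) > 0))
})

test_that("C optimization matches exhaustive explicit LOO refits", {
  set.seed(34)
  d <- matrix(rnorm(15 * 3), 15, 3)
  y <- d %*% c(1, -1, 0.5) + rnorm(15, sd = 0.8)
  dc <- sweep(d, 2, colMeans(d))
  yc <- drop(y - mean(y))
  grid <- 2^seq(-6, 12, 2)
  press <- vapply(grid, function(c_value) {
    mean(vapply(seq_len(15), function(i) {
      b <- solve(crossprod(dc[-i, ]) + diag(3) / c_value,
                 crossprod(dc[-i, ], yc[-i]))
      (yc[i] - drop(dc[i, ] %*% b))^2
    }, numeric(1)))
  }, numeric(1))
  opt <- optimize_c(dc, yc, grid)
  expect_equal(opt$c_value, grid[which.min(press)])
  expect_equal(opt$path$e_loo, press, tolerance = 1e-8)

  # a one-value grid returns that value
  expect_equal(optimize_c(dc, yc, 4)$c_value, 4)
})

test_that("the C grid reuses a single SVD", {
  set.seed(35)
  d <- matrix(rnorm(20 * 4), 20, 4)
  y <- rnorm(20)
  calls <- 0L
  testthat::local_mocked_bindings(
    .svd_econ = function(x) { calls <<- calls + 1L; svd(x) },
    .package = "skelage"
  )
  optimize_c(d, y, 2^seq(-6, 12, 2))
  expect_identical(calls, 1L)
})

test_that("fitting is deterministic and nails a noiseless linear target", {
  set.seed(36)
  x <- matrix(sample(0:2, 128 * 3, replace = TRUE), 128, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  y <- 30 + 15 * x[, 1]
  f1 <- drnn_fit(x, y, seed = 2)
  f2 <- drnn_fit(x, y, seed = 2)
  expect_identical(f1$loo_predictions, f2$loo_predictions)
  expect_lt(mean(abs(y - f1$loo_predictions)), 0.5)

  expect_error(drnn_fit(x, rep(50, 128), seed = 1), "constant")
})

test_that("design width and depth follow the concatenation arithmetic", {
  sim <- simulate_skeletal(generator_config(n = 500, seed = 40))
  obs <- impute_nn1_jaccard(sim$obs, sim$schema)
  fit <- drnn_fit(obs, seed = 40)
  expect_identical(fit$architecture$depth, 8L)
  # D(L) columns: L * width + inputs = 256 + 64
  expect_identical(length(fit$solutions[[8]]$cols), 320L)
  expect_identical(length(fit$solutions[[1]]$cols), 32L + 64L)
  # per-depth C values come from the default grid
  for (sol in fit$solutions) expect_true(sol$c_value %in% 2^seq(-6, 12, 2))
})

test_that("depth-1 override yields a shallow RVFL network", {
  set.seed(37)
  x <- matrix(sample(0:1, 60 * 4, replace = TRUE), 60, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  y <- 20 + 10 * x[, 1] + 5 * x[, 2] + rnorm(60)
  fit <- drnn_fit(x, y, seed = 3, depth = 1L, width = 16L)
  expect_identical(length(fit$solutions), 1L)
  expect_identical(length(fit$solutions[[1]]$cols), 16L + 4L)
})

test_that("prediction averages depths, respects column order, bounds sanity", {
  sim <- simulate_skeletal(generator_config(n = 200, seed = 41))
  obs <- impute_nn1_jaccard(sim$obs, sim$schema)
  fit <- drnn_fit(obs, seed = 41)

  # training rows reproduce the stored fitted ensemble
  expect_equal(predict(fit, obs), fit$fitted, tolerance = 1e-10)

  # permuting trait columns leaves predictions unchanged
  perm <- sample(ncol(obs$stages))
  shuffled <- obs$stages[1:5, perm, drop = FALSE]
  expect_equal(predict(fit, shuffled), predict(fit, obs$stages[1:5, ]),
               tolerance = 1e-12)

  # a constant-stage row predicts within the training range +/- slack
  row0 <- obs$stages[1, , drop = FALSE]
  row0[] <- 0L
  p0 <- predict(fit, row0)
  expect_gt(p0, fit$age_range[1] - 20)
  expect_lt(p0, fit$age_range[2] + 20)

  expect_error(predict(fit, obs$stages[, 1:10]), "lacks trait")
})

test_that("output-layer designs stay below the PRESS degeneracy threshold", {
  # with >= n - 1 centered columns the analytic LOO error collapses to
  # zero regardless of generalization; the fit must cap the design
  sim <- simulate_skeletal(generator_config(n = 160, seed = 44))
  obs <- impute_nn1_jaccard(sim$obs, sim$schema)
  fit <- drnn_fit(obs, seed = 44)
  max_cols <- max(vapply(fit$solutions, function(s) length(s$cols), integer(1)))
  expect_lte(max_cols, 160 - 2)
  expect_true(all(vapply(fit$solutions, `[[`, numeric(1), "e_loo") > 1e-6))
  # LOO error remains an honest estimate: held-out error of the same
  # order, not an order of magnitude worse
  sim2 <- simulate_skeletal(generator_config(n = 50, seed = 45))
  te <- impute_nn1_jaccard(sim2$obs, sim2$schema)
  expect_lt(mean(abs(te$ages - predict(fit, te))), 3 * fit$loo_mae)
})

test_that("cross-validated MAE beats the mean-age baseline on informative data", {
  sim <- simulate_skeletal(generator_config(n = 300, seed = 42))
  obs <- impute_nn1_jaccard(sim$obs, sim$schema)
  fit <- drnn_fit(obs, seed = 42)
  baseline <- mean(abs(obs$ages - mean(obs$ages)))
  expect_lt(fit$loo_mae, baseline / 2)
})
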