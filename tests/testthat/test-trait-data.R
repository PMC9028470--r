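test_that("laterality collapse prefers the left side with right as surrogate", {
  sch <- trait_schema(data.frame(
    trait_id = c("B1", "U1"), n_stages = 3,
    bilateral = c(TRUE, FALSE), block = "appendicular"
  ))
  raw <- observation_matrix(matrix(
    c(2L, NA, NA,   # B1.L
      1L, 1L, NA,   # B1.R
      0L, 2L, 1L),  # U1
    nrow = 3, dimnames = list(NULL, c("B1.L", "B1.R", "U1"))
  ))
  out <- as.matrix(collapse_laterality(raw, sch))
  expect_identical(unname(out[, "B1"]), c(2L, 1L, NA))  # left, surrogate, missing
  expect_identical(unname(out[, "U1"]), c(0L, 2L, 1L))  # unilateral pass-through
})

test_that("collapse reduces a full side-tagged panel from 99 to 64 columns", {
  panel <- default_trait_panel()
  expect_identical(sum(panel$bilateral), 35L)
  expect_identical(nrow(panel), 64L)
  sim <- simulate_skeletal(generator_config(n = 30, seed = 1))
  expect_identical(ncol(sim$raw$stages), 99L)
  expect_identical(ncol(sim$obs$stages), 64L)
})

test_that("collapse never introduces a value absent from the left/right pair", {
  panel <- default_trait_panel()
  sim <- simulate_skeletal(generator_config(n = 60, seed = 8))
  raw <- sim$raw$stages
  out <- sim$obs$stages
  for (tid in panel$trait_id[panel$bilateral]) {
    l <- raw[, paste0(tid, ".L")]
    r <- raw[, paste0(tid, ".R")]
    v <- out[, tid]
    ok <- is.na(v) | (v == l & !is.na(l)) | (v == r & !is.na(r))
    expect_true(all(ok))
  }
})

test_that("collapse rejects malformed bilateral columns", {
  sch <- trait_schema(data.frame(trait_id = "B1", n_stages = 2,
                                 bilateral = TRUE, block = "clavicle"))
  raw <- matrix(0L, 2, 3, dimnames = list(NULL, c("B1.L", "B1.R", "B1")))
  expect_error(collapse_laterality(observation_matrix(raw), sch),
               "more than two")
})

test_that("one-hot encoding follows the indicator definition and masks missing", {
  sch <- make_schema(2, n_stages = c(3L, 2L))
  x <- matrix(c(1L, NA, 0L, NA), 2, dimnames = list(NULL, c("T01", "T02")))
  enc <- one_hot_encode(observation_matrix(x), sch)
  expect_identical(unname(enc$indicators[1, 1:3]), c(0L, 1L, 0L))
  expect_identical(unname(enc$indicators[2, 1:3]), c(0L, 0L, 0L))
  expect_identical(unname(enc$indicators[2, 4:5]), c(0L, 0L))
  expect_true(enc$missing[2, "T01"])
  expect_true(enc$missing[2, "T02"])
  expect_false(enc$missing[1, "T01"])
})

test_that("one-hot encode/decode is a bijection on complete valid matrices", {
  for (seed in 1:3) {
    sch <- make_schema(6, n_stages = c(2L, 3L, 2L, 3L, 3L, 2L))
    x <- rand_stages(15, sch, seed)
    enc <- one_hot_encode(observation_matrix(x), sch)
    expect_identical(one_hot_decode(enc), x)
  }
})

test_that("encoding rejects out-of-range stage codes", {
  sch <- make_schema(1, n_stages = 2L)
  x <- matrix(2L, 1, 1, dimnames = list(NULL, "T01"))
  expect_error(one_hot_encode(x, sch), "out of range")
})

test_that("1-NN Jaccard imputation picks the forced donor", {
  sch <- make_schema(3, n_stages = 2L)
  x <- matrix(c(1L, 0L, 1L,
                1L, 0L, NA,
                0L, 1L, 0L), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), sch$trait_id))
  out <- as.matrix(impute_nn1_jaccard(observation_matrix(x), sch))
  # B matches A (Jaccard 1 on shared traits) not C (Jaccard 0)
  expect_identical(unname(out["B", ]), c(1L, 0L, 1L))
  # observed values untouched
  expect_identical(out[c("A", "C"), ], x[c("A", "C"), ])
})

test_that("imputation on a complete matrix is the identity", {
  sch <- make_schema(5, n_stages = 3L)
  x <- rand_stages(12, sch, 4)
  out <- impute_nn1_jaccard(observation_matrix(x), sch)
  expect_identical(as.matrix(out), x)
})

test_that("imputation matches an exhaustive donor search", {
  sch <- make_schema(10, n_stages = rep(c(2L, 3L), 5))
  for (seed in c(2, 9, 17)) {
    x <- rand_stages(20, sch, seed)
    set.seed(seed + 100)
    holes <- cbind(sample(20, 3), sample(10, 3))
    x[holes] <- NA
    out <- as.matrix(impute_nn1_jaccard(observation_matrix(x), sch))
    for (r in unique(holes[, 1])) {
      sims <- vapply(seq_len(20), function(d) {
        if (d == r) return(-Inf)
        need <- which(is.na(x[r, ]))
        if (anyNA(x[d, need])) return(-Inf)
        oracle_jaccard(x[r, ], x[d, ], sch$n_stages)
      }, numeric(1))
      donor <- which.max(sims)  # ties -> lowest index
      need <- which(is.na(x[r, ]))
      expect_identical(out[r, need], x[donor, need])
    }
  }
})

test_that("imputation is idempotent", {
  sch <- make_schema(8, n_stages = 3L)
  x <- rand_stages(25, sch, 6)
  set.seed(7)
  x[sample(length(x), 30)] <- NA
  once <- impute_nn1_jaccard(observation_matrix(x), sch)
  twice <- impute_nn1_jaccard(once, sch)
  expect_identical(as.matrix(twice), as.matrix(once))
})

test_that("imputation errors are informative", {
  sch <- make_schema(2, n_stages = 2L)
  x <- matrix(c(NA, 1L, NA, 0L), 2, dimnames = list(c("A", "B"), sch$trait_id))
  expect_error(impute_nn1_jaccard(observation_matrix(x), sch), "cannot match")
  y <- matrix(c(1L, 0L, NA, NA), 2, dimnames = list(c("A", "B"), sch$trait_id))
  expect_error(impute_nn1_jaccard(observation_matrix(y), sch), "no donor")
})

test_that("test rows can be imputed from training donors only", {
  sch <- make_schema(6, n_stages = 2L)
  train <- observation_matrix(rand_stages(30, sch, 3))
  te <- rand_stages(5, sch, 13)
  te[1, 2] <- NA
  out <- impute_nn1_jaccard(observation_matrix(te), sch, donors = train)
  expect_false(anyNA(as.matrix(out)))
  expect_true(out$stages[1, 2] %in% train$stages[, 2])
})

test_that("Kendall's W is 1 for identical and 0 for reversed sessions", {
  a <- matrix(c(0, 1, 2, 2, 1, 0, 1, 1), 4,
              dimnames = list(NULL, c("T1", "T2")))
  rep_same <- kendalls_w(a, a)
  expect_equal(rep_same$traits$W, c(1, 1))
  expect_equal(rep_same$mean_w, 1)

  x <- matrix(1:6, 6, 1, dimnames = list(NULL, "T1"))
  y <- matrix(6:1, 6, 1, dimnames = list(NULL, "T1"))
  expect_equal(kendalls_w(x, y)$traits$W, 0)
})

test_that("Kendall's W matches an independent rank-sum computation with ties", {
  set.seed(21)
  a <- matrix(sample(0:2, 50, replace = TRUE), 50, 1,
              dimnames = list(NULL, "T1"))
  b <- matrix(sample(0:2, 50, replace = TRUE), 50, 1,
              dimnames = list(NULL, "T1"))
  got <- kendalls_w(a, b)$traits

  # from-scratch: rank sums, tie corrections, W = 12S / (m^2(n^3-n) - m*sum T)
  n <- 50; m <- 2
  ra <- rank(a[, 1]); rb <- rank(b[, 1])
  ties <- function(r) { tt <- table(r); sum(tt^3 - tt) }
  s <- sum((ra + rb - mean(ra + rb))^2)
  w_oracle <- 12 * s / (m^2 * (n^3 - n) - m * (ties(ra) + ties(rb)))
  expect_equal(got$W, w_oracle, tolerance = 1e-12)
  expect_equal(got$chisq, m * (n - 1) * w_oracle, tolerance = 1e-12)
  expect_gte(got$W, 0)
  expect_lte(got$W, 1)
})

test_that("Kendall's W edge cases: too few subjects, constant ratings", {
  a <- matrix(0, 2, 1, dimnames = list(NULL, "T1"))
  expect_error(kendalls_w(a, a), "3 subjects")
  const <- matrix(1, 5, 1, dimnames = list(NULL, "T1"))
  expect_true(is.na(kendalls_w(const, const)$traits$W))
})

test_that("trait CSV and schema files round-trip", {
  sch <- make_schema(4, n_stages = c(2L, 3L, 2L, 3L))
  x <- rand_stages(10, sch, 5)
  x[2, 3] <- NA
  obs <- observation_matrix(x, ages = seq(20, 65, length.out = 10))
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_traits(obs, csv)
  write_schema(sch, yml)
  obs2 <- read_traits(csv, schema = read_schema(yml))
  expect_identical(obs2$stages, obs$stages)
  expect_equal(obs2$ages, obs$ages)
})
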