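#' Configuration for the synthetic skeletal-trait generator
#'
#' Describes a synthetic study population for the ordinal-trait
#' generator: adult ages uniform on a range, a latent senescence score
#' per individual (standardized age plus Gaussian frailty), and ordinal
#' traits produced by an ordered-probit link of configurable strength.
#' Defaults emulate the statistical structure of a 500-skeleton
#' identified reference collection: ages uniform on 19-101 years, the
#' 64-trait panel of [default_trait_panel()] with bilateral redundancy
#' (99 raw side-tagged columns), and 9.5% missing cells completely at
#' random.
#'
#' @param n number of individuals.
#' @param age_range numeric length-2, uniform age-at-death range (years).
#' @param traits a `trait_schema` with a `lambda` column (informativeness
#'   of each trait's monotone age link; `lambda = 0` is pure noise).
#' @param frailty_sd SD of the Gaussian frailty added to standardized age
#'   in the latent senescence score (individual variation in senescence
#'   pace, on the standardized-age scale).
#' @param disagreement_prob probability that a bilateral trait's right
#'   side flips to an adjacent stage relative to the left.
#' @param missing_rate per-cell missingness probability (MCAR) applied to
#'   the raw side-tagged table.
#' @param seed integer RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 500, age_range = c(19, 101),
                             traits = default_trait_panel(),
                             frailty_sd = 0.3, disagreement_prob = 0.05,
                             missing_rate = 0.095, seed = 1L) {
  stopifnot(inherits(traits, "trait_schema"))
  if (!"lambda" %in% names(traits)) {
    stop("traits must carry a lambda column (link strength)")
  }
  if (any(traits$lambda < 0) || any(!is.finite(traits$lambda))) {
    stop("lambda must be finite and >= 0")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (disagreement_prob < 0 || disagreement_prob > 1) {
    stop("disagreement_prob must be in [0, 1]")
  }
  if (age_range[1] >= age_range[2]) stop("age_range must be increasing")
  structure(list(n = as.integer(n), age_range = age_range, traits = traits,
                 frailty_sd = frailty_sd,
                 disagreement_prob = disagreement_prob,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic skeletal-trait dataset
#'
#' Draws ages uniformly on the configured range; forms a latent
#' senescence score `s_i = z_i + frailty` where `z_i` is age standardized
#' to unit variance under the uniform; produces each trait by an
#' ordered-probit link — latent value `lambda_k * s_i + N(0, 1)` cut at
#' the equal-mass quantiles of its marginal distribution, mapped to
#' stages `0..n_stages-1` (so stages are roughly balanced and mean stage
#' increases monotonically with age whenever `lambda_k > 0`). Bilateral
#' traits copy the left stage to the right, flipped to an adjacent stage
#' with the configured disagreement probability. Cells of the raw
#' side-tagged table are then masked missing completely at random.
#'
#' @param config a [generator_config()].
#' @return A list with `raw` (side-tagged `obs_matrix`, one `.L`/`.R`
#'   column pair per bilateral trait), `obs` (the laterality-collapsed
#'   `obs_matrix`, one column per trait), `schema` (the `trait_schema`),
#'   and `truth` (ages, latent senescence, `lambda`, and the cut-points
#'   per trait).
#' @export
#' @examples
#' sim <- simulate_skeletal(generator_config(n = 50, seed = 42))
#' sim$obs
simulate_skeletal <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  traits <- config$traits
  n <- config$n
  set.seed(config$seed)

  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  # standardize age to unit variance under the uniform distribution
  mu <- mean(config$age_range)
  sd_u <- diff(config$age_range) / sqrt(12)
  z <- (ages - mu) / sd_u
  s <- z + stats::rnorm(n, 0, config$frailty_sd)

  m <- nrow(traits)
  left <- matrix(NA_integer_, n, m, dimnames = list(NULL, traits$trait_id))
  cuts <- vector("list", m)
  names(cuts) <- traits$trait_id
  for (k in seq_len(m)) {
    lam <- traits$lambda[k]
    latent <- lam * s + stats::rnorm(n)
    sd_lat <- sqrt(lam^2 * (1 + config$frailty_sd^2) + 1)
    kk <- traits$n_stages[k]
    cp <- stats::qnorm(seq_len(kk - 1L) / kk, mean = 0, sd = sd_lat)
    if (any(!is.finite(cp)) || any(diff(cp) <= 0) && kk > 2L) {
      stop("degenerate cut-points for trait ", traits$trait_id[k])
    }
    left[, k] <- as.integer(findInterval(latent, cp))
    cuts[[k]] <- cp
  }

  # assemble the raw side-tagged table
  raw_cols <- vector("list", m)
  for (k in seq_len(m)) {
    tid <- traits$trait_id[k]
    if (traits$bilateral[k]) {
      right <- left[, k]
      flip <- stats::runif(n) < config$disagreement_prob
      if (any(flip)) {
        step <- ifelse(stats::runif(sum(flip)) < 0.5, -1L, 1L)
        moved <- right[flip] + step
        moved <- pmin(pmax(moved, 0L), traits$n_stages[k] - 1L)
        # at a boundary, "adjacent" can only go inward
        at_edge <- moved == right[flip]
        moved[at_edge] <- right[flip][at_edge] - step[at_edge]
        right[flip] <- moved
      }
      raw_cols[[k]] <- matrix(c(left[, k], right), n, 2,
                              dimnames = list(NULL, paste0(tid, c(".L", ".R"))))
    } else {
      raw_cols[[k]] <- matrix(left[, k], n, 1, dimnames = list(NULL, tid))
    }
  }
  raw <- do.call(cbind, raw_cols)
  rownames(raw) <- sprintf("ind%03d", seq_len(n))

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(raw)) < config$missing_rate,
                   nrow(raw), ncol(raw))
    raw[mask] <- NA_integer_
  }

  raw_obs <- observation_matrix(raw, ages = ages)
  obs <- collapse_laterality(raw_obs, traits)
  list(raw = raw_obs, obs = obs, schema = traits,
       truth = list(ages = ages, senescence = s,
                    lambda = stats::setNames(traits$lambda, traits$trait_id),
                    cut_points = cuts, seed = config$seed))
}
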