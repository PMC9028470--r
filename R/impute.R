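#' 1-nearest-neighbour imputation with Jaccard similarity
#'
#' Fills every missing observation of an individual from a single donor:
#' the individual (or training donor) with the highest Jaccard similarity,
#' computed on one-hot indicator bits restricted to traits observed in
#' BOTH individuals. All of a recipient's missing values are copied from
#' that one donor, so the donated pattern stays internally coherent —
#' substituting whole nearest-neighbour profiles preserves the structure
#' of ordinal trait data better than cell-wise model-based imputation.
#' Observed values are never altered. Similarity ties break to the lowest
#' donor index, making the procedure deterministic.
#'
#' @param obs an `obs_matrix` (or stage matrix) to complete.
#' @param schema a `trait_schema` covering the columns of `obs`.
#' @param donors optional `obs_matrix` of donor individuals (e.g. the
#'   training partition when imputing test rows). Defaults to `obs`
#'   itself, excluding each recipient as its own donor.
#' @return A complete `obs_matrix` (no `NA` entries), same shape as `obs`.
#' @export
#' @examples
#' sch <- trait_schema(data.frame(trait_id = c("A", "B", "C"), n_stages = 2,
#'                                bilateral = FALSE, block = "axial"))
#' x <- matrix(c(1L, 1L, 0L, 0L, 0L, 1L, 1L, NA, 0L), 3,
#'             dimnames = list(NULL, c("A", "B", "C")))
#' as.matrix(impute_nn1_jaccard(observation_matrix(x), sch))
impute_nn1_jaccard <- function(obs, schema, donors = NULL) {
  stages <- .stages(obs)
  validate_stages(stages, schema)
  self_donors <- is.null(donors)
  donor_stages <- if (self_donors) stages else .stages(donors)
  if (!identical(colnames(donor_stages), colnames(stages))) {
    stop("donor matrix must have the same traits in the same order")
  }
  validate_stages(donor_stages, schema)

  recipients <- which(rowSums(is.na(stages)) > 0L)
  out <- stages
  if (length(recipients)) {
    donor_obs <- !is.na(donor_stages)
    for (r in recipients) {
      x <- stages[r, ]
      obs_r <- !is.na(x)
      if (!any(obs_r)) {
        stop("cannot match: individual ", rownames(stages)[r],
             " has no observed traits")
      }
      need <- which(!obs_r)
      # donors must cover every trait the recipient is missing
      eligible <- rowSums(donor_obs[, need, drop = FALSE]) == length(need)
      if (self_donors) eligible[r] <- FALSE
      if (!any(eligible)) {
        stop("no donor observes all traits missing for individual ",
             rownames(stages)[r])
      }
      # Jaccard on one-hot bits over traits observed in both: each shared
      # trait contributes |intersection| 1 and |union| 1 if stages agree,
      # 0 and 2 if they disagree, so J = agree / (agree + 2 * disagree).
      shared <- donor_obs[, obs_r, drop = FALSE]
      agree <- shared & (donor_stages[, obs_r, drop = FALSE] ==
                           rep(x[obs_r], each = nrow(donor_stages)))
      a <- rowSums(agree)
      d <- rowSums(shared) - a
      sim <- ifelse(a + d > 0L, a / (a + 2 * d), -Inf)
      sim[!eligible] <- -Inf
      if (all(!is.finite(sim))) {
        stop("no donor shares an observed trait with individual ",
             rownames(stages)[r])
      }
      best <- which.max(sim)  # ties -> lowest index
      out[r, need] <- donor_stages[best, need]
    }
  }
  ages <- if (inherits(obs, "obs_matrix")) obs$ages else NULL
  observation_matrix(out, ages = ages, schema = schema)
}
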