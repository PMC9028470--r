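# shared fixtures, built in code

# minimal schema: m unilateral traits in one block, optional lambda
make_schema <- function(m, n_stages = 2L, bilateral = FALSE, block = "axial",
                        lambda = NULL) {
  df <- data.frame(
    trait_id = sprintf("T%02d", seq_len(m)),
    n_stages = rep_len(n_stages, m),
    bilateral = rep_len(bilateral, m),
    block = rep_len(block, m),
    stringsAsFactors = FALSE
  )
  if (!is.null(lambda)) df$lambda <- rep_len(lambda, m)
  trait_schema(df)
}

# random complete stage matrix consistent with a schema
rand_stages <- function(n, schema, seed) {
  set.seed(seed)
  m <- nrow(schema)
  x <- vapply(seq_len(m), function(j) {
    sample.int(schema$n_stages[j], n, replace = TRUE) - 1L
  }, integer(n))
  dimnames(x) <- list(sprintf("i%03d", seq_len(n)), schema$trait_id)
  x
}

# independent Jaccard similarity on one-hot bits over traits observed in
# both individuals (hand-rolled oracle, no package code)
oracle_jaccard <- function(x, y, n_stages) {
  inter <- 0L
  union <- 0L
  for (j in seq_along(x)) {
    if (is.na(x[j]) || is.na(y[j])) next
    bits_x <- as.integer(seq_len(n_stages[j]) - 1L == x[j])
    bits_y <- as.integer(seq_len(n_stages[j]) - 1L == y[j])
    inter <- inter + sum(bits_x & bits_y)
    union <- union + sum(bits_x | bits_y)
  }
  if (union == 0L) return(-Inf)
  inter / union
}
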