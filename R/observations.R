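#' Ordinal trait observation matrix
#'
#' Container for individuals x traits ordinal stage observations. Stages
#' are 0-based integer codes ("Stage 0/1/2"); missing observations are
#' `NA`. Known ages-at-death, when available, ride along as a numeric
#' vector aligned with the rows.
#'
#' @param stages integer matrix or data.frame of stage codes with `NA`
#'   for missing; rownames are individual ids, colnames are trait ids
#'   (optionally side-tagged `".L"`/`".R"` before laterality collapse).
#' @param ages optional numeric vector of known ages (years), finite and
#'   non-negative, one per row.
#' @param schema optional `trait_schema`; when supplied, every non-missing
#'   stage is checked against the trait's stage count.
#' @return An object of class `obs_matrix`: a list with elements `stages`
#'   (integer matrix), `ages`, `ids`, `traits`.
#' @export
#' @examples
#' m <- observation_matrix(matrix(c(0L, 1L, NA, 2L), 2,
#'                                dimnames = list(c("a", "b"), c("T1", "T2"))),
#'                         ages = c(25, 60))
#' dim(m)
observation_matrix <- function(stages, ages = NULL, schema = NULL) {
  if (is.data.frame(stages)) stages <- as.matrix(stages)
  storage.mode(stages) <- "integer"
  if (is.null(rownames(stages))) rownames(stages) <- as.character(seq_len(nrow(stages)))
  if (is.null(colnames(stages))) {
    stop("stage matrix must have trait ids as column names")
  }
  if (!is.null(ages)) {
    ages <- as.numeric(ages)
    if (length(ages) != nrow(stages)) {
      stop("ages must have one value per individual")
    }
    if (any(!is.finite(ages)) || any(ages < 0)) {
      stop("ages must be finite and non-negative")
    }
  }
  obs <- structure(
    list(stages = stages, ages = ages,
         ids = rownames(stages), traits = colnames(stages)),
    class = "obs_matrix"
  )
  if (!is.null(schema)) validate_stages(obs, schema)
  obs
}

#' @export
dim.obs_matrix <- function(x) dim(x$stages)

#' @export
print.obs_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$stages))
  cat(sprintf(
    "<obs_matrix> %d individuals x %d traits (%.1f%% missing)%s\n",
    nrow(x$stages), ncol(x$stages),
    100 * n_missing / length(x$stages),
    if (is.null(x$ages)) "" else ", ages attached"
  ))
  invisible(x)
}

#' @export
as.matrix.obs_matrix <- function(x, ...) x$stages

# accept either an obs_matrix or a plain matrix
.stages <- function(x) {
  if (inherits(x, "obs_matrix")) x$stages else as.matrix(x)
}

#' Validate stage codes against a schema
#'
#' Checks that every non-missing stage `s` of trait `t` satisfies
#' `0 <= s < n_stages(t)`. Side-tagged columns (`".L"`/`".R"`) are
#' validated against their base trait.
#'
#' @param obs an `obs_matrix` or stage matrix.
#' @param schema a `trait_schema`.
#' @return `obs`, invisibly, if valid; otherwise an error.
#' @export
validate_stages <- function(obs, schema) {
  stages <- .stages(obs)
  base <- sub("\\.(L|R)$", "", colnames(stages))
  unknown <- setdiff(base, schema$trait_id)
  if (length(unknown)) {
    stop("columns not in schema: ", paste(unique(unknown), collapse = ", "))
  }
  n_stages <- schema$n_stages[match(base, schema$trait_id)]
  for (j in seq_along(base)) {
    s <- stages[, j]
    bad <- !is.na(s) & (s < 0L | s >= n_stages[j])
    if (any(bad)) {
      stop(sprintf("trait %s: stage code out of range [0, %d) for %d row(s)",
                   colnames(stages)[j], n_stages[j], sum(bad)))
    }
  }
  invisible(obs)
}

#' Read / write a trait observation table
#'
#' CSV layout: first column is the individual id, one column per trait
#' observation with header equal to the trait id (with an optional
#' `".L"`/`".R"` suffix for side-tagged bilateral observations), and an
#' optional `age` column with known age-at-death. Empty cells and `"NA"`
#' both denote missing observations.
#'
#' @param path file path.
#' @param schema optional `trait_schema` for stage validation.
#' @return `read_traits()` returns an `obs_matrix`.
#' @export
read_traits <- function(path, schema = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("trait CSV needs an id column plus trait columns")
  ids <- as.character(tab[[1L]])
  tab <- tab[, -1L, drop = FALSE]
  ages <- NULL
  if ("age" %in% names(tab)) {
    ages <- as.numeric(tab[["age"]])
    tab <- tab[, names(tab) != "age", drop = FALSE]
  }
  stages <- as.matrix(tab)
  rownames(stages) <- ids
  observation_matrix(stages, ages = ages, schema = schema)
}

#' @rdname read_traits
#' @param obs an `obs_matrix`.
#' @export
write_traits <- function(obs, path) {
  stopifnot(inherits(obs, "obs_matrix"))
  out <- data.frame(id = obs$ids, obs$stages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(obs$ages)) out$age <- obs$ages
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Collapse bilateral observations to one column per trait
#'
#' For bilateral traits scored on both sides, the left side is the main
#' source of data; where the left score is missing the right side is used
#' as a surrogate; where both are missing the trait stays missing.
#' Unilateral columns pass through unchanged. The result has exactly one
#' column per schema trait, in schema order.
#'
#' @param raw an `obs_matrix` whose bilateral traits appear as `".L"` /
#'   `".R"`-suffixed columns.
#' @param schema a `trait_schema`.
#' @return An `obs_matrix` with `nrow(schema)` columns.
#' @export
#' @examples
#' sch <- trait_schema(data.frame(trait_id = c("A", "B"),
#'                                n_stages = 2, bilateral = c(TRUE, FALSE),
#'                                block = "appendicular"))
#' raw <- observation_matrix(
#'   matrix(c(NA, 1L, 0L, NA, 1L, 0L), 2,
#'          dimnames = list(NULL, c("A.L", "A.R", "B"))))
#' as.matrix(collapse_laterality(raw, sch))
collapse_laterality <- function(raw, schema) {
  stopifnot(inherits(schema, "trait_schema"))
  stages <- .stages(raw)
  cols <- colnames(stages)
  base <- sub("\\.(L|R)$", "", cols)
  out <- matrix(NA_integer_, nrow(stages), nrow(schema),
                dimnames = list(rownames(stages), schema$trait_id))
  for (i in seq_len(nrow(schema))) {
    tid <- schema$trait_id[i]
    hit <- which(base == tid)
    if (!length(hit)) next
    if (schema$bilateral[i]) {
      if (length(hit) > 2L) {
        stop("bilateral trait ", tid, " has more than two tagged columns")
      }
      left <- hit[grepl("\\.L$", cols[hit])]
      right <- hit[grepl("\\.R$", cols[hit])]
      if (length(left) + length(right) != length(hit)) {
        stop("bilateral trait ", tid, " has an untagged column")
      }
      val <- if (length(left)) stages[, left] else rep(NA_integer_, nrow(stages))
      if (length(right)) {
        fill <- is.na(val)
        val[fill] <- stages[fill, right]
      }
      out[, tid] <- val
    } else {
      if (length(hit) > 1L) {
        stop("unilateral trait ", tid, " appears in multiple columns")
      }
      out[, tid] <- stages[, hit]
    }
  }
  ages <- if (inherits(raw, "obs_matrix")) raw$ages else NULL
  observation_matrix(out, ages = ages, schema = schema)
}

#' One-hot encode an observation matrix
#'
#' Each trait expands into `n_stages` indicator columns; a missing stage
#' yields all-zero indicators for that trait and a set bit in the missing
#' mask. The column map makes the encoding invertible.
#'
#' @param obs an `obs_matrix` or stage matrix.
#' @param schema a `trait_schema` covering every column of `obs`.
#' @return A list with `indicators` (binary matrix), `map` (data.frame
#'   with `column`, `trait_id`, `stage`), and `missing` (logical matrix,
#'   individuals x traits).
#' @export
one_hot_encode <- function(obs, schema) {
  stopifnot(inherits(schema, "trait_schema"))
  validate_stages(obs, schema)
  stages <- .stages(obs)
  traits <- colnames(stages)
  n_stages <- schema$n_stages[match(traits, schema$trait_id)]
  total <- sum(n_stages)
  ind <- matrix(0L, nrow(stages), total)
  map <- data.frame(
    column = seq_len(total),
    trait_id = rep(traits, n_stages),
    stage = unlist(lapply(n_stages, function(k) 0:(k - 1L))),
    stringsAsFactors = FALSE
  )
  colnames(ind) <- paste0(map$trait_id, "=", map$stage)
  rownames(ind) <- rownames(stages)
  offset <- c(0L, cumsum(n_stages))
  for (j in seq_along(traits)) {
    s <- stages[, j]
    seen <- which(!is.na(s))
    ind[cbind(seen, offset[j] + s[seen] + 1L)] <- 1L
  }
  missing <- is.na(stages)
  list(indicators = ind, map = map, missing = missing)
}

#' Decode a one-hot encoding back to stage codes
#'
#' @param encoded the list returned by [one_hot_encode()].
#' @return An integer stage matrix with `NA` where the mask was set.
#' @export
one_hot_decode <- function(encoded) {
  map <- encoded$map
  ind <- encoded$indicators
  traits <- unique(map$trait_id)
  out <- matrix(NA_integer_, nrow(ind), length(traits),
                dimnames = list(rownames(ind), traits))
  for (tid in traits) {
    cols <- map$column[map$trait_id == tid]
    block <- ind[, cols, drop = FALSE]
    on <- block %*% (map$stage[map$trait_id == tid])
    hit <- rowSums(block) == 1L
    out[hit, tid] <- as.integer(on[hit])
  }
  out[encoded$missing[, traits, drop = FALSE]] <- NA_integer_
  out
}
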