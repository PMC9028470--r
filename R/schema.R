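#' Trait schema
#'
#' A trait schema describes the ordinal skeletal traits a dataset may
#' contain: a unique trait id, the number of expression stages (2 or 3,
#' scored 0-based), whether the trait is bilateral (scored on left and
#' right sides), and the anatomical block it belongs to. The schema is the
#' contract against which observation matrices are validated and the
#' handle by which anatomical-block presets (e.g. "sutures", "standard")
#' are resolved.
#'
#' @param traits data.frame with columns `trait_id` (character, unique),
#'   `n_stages` (integer, 2 or 3), `bilateral` (logical), `block`
#'   (character, one of the recognised anatomical blocks). Extra columns
#'   are preserved.
#' @return An object of class `trait_schema` (a validated data.frame).
#' @export
#' @examples
#' trait_schema(data.frame(trait_id = "PS01", n_stages = 3,
#'                         bilateral = TRUE, block = "pubic_symphysis"))
trait_schema <- function(traits) {
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  required <- c("trait_id", "n_stages", "bilateral", "block")
  missing_cols <- setdiff(required, names(traits))
  if (length(missing_cols)) {
    stop("schema is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  traits$trait_id <- as.character(traits$trait_id)
  traits$n_stages <- as.integer(traits$n_stages)
  traits$bilateral <- as.logical(traits$bilateral)
  traits$block <- as.character(traits$block)
  if (anyDuplicated(traits$trait_id)) {
    stop("trait_id values must be unique within a schema")
  }
  if (!all(traits$n_stages %in% c(2L, 3L))) {
    stop("n_stages must be 2 or 3 for every trait")
  }
  if (anyNA(traits$bilateral)) stop("bilateral flags must be TRUE/FALSE")
  bad <- setdiff(unique(traits$block), skeletal_blocks())
  if (length(bad)) {
    stop("unknown anatomical block(s): ", paste(bad, collapse = ", "),
         "; valid blocks: ", paste(skeletal_blocks(), collapse = ", "))
  }
  class(traits) <- c("trait_schema", "data.frame")
  traits
}

#' Recognised anatomical blocks
#'
#' @return Character vector of block labels a schema may use.
#' @export
skeletal_blocks <- function() {
  c("sutures", "axial", "appendicular", "clavicle", "first_rib",
    "pubic_symphysis", "sacroiliac", "acetabulum")
}

#' Read / write a trait schema
#'
#' Schemas are stored as YAML: a sequence of records each with keys
#' `trait_id`, `n_stages`, `bilateral`, `block` (additional keys such as
#' the synthetic generator's `lambda` are carried through).
#'
#' @param path file path.
#' @return `read_schema()` returns a `trait_schema`; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  records <- yaml::read_yaml(path)
  if (!length(records)) stop("empty schema file: ", path)
  trait_schema(do.call(rbind, lapply(records, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  })))
}

#' @rdname read_schema
#' @param schema a `trait_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "trait_schema"))
  records <- lapply(seq_len(nrow(schema)), function(i) {
    r <- as.list(schema[i, , drop = FALSE])
    lapply(r, function(v) if (is.factor(v)) as.character(v) else unname(v))
  })
  yaml::write_yaml(records, path)
  invisible(path)
}

#' Default synthetic 64-trait panel
#'
#' A synthetic stand-in for a full multifactorial macroscopic scoring
#' panel: 64 unique traits across the eight anatomical blocks (9 cranial/
#' palatine sutures, 16 axial vertebral traits, 23 appendicular joint and
#' entheseal traits, 2 clavicle, 2 first rib, 3 pubic symphysis, 6
#' sacroiliac, 3 acetabulum), of which 35 are bilateral — so a raw
#' side-tagged observation table has 29 + 2*35 = 99 columns. Each trait
#' carries a `lambda` column: the strength of its monotone link to age
#' used by [simulate_skeletal()]; block-level defaults span weak (sutures)
#' to strong (axial) associations.
#'
#' @return A `trait_schema` with an extra numeric `lambda` column.
#' @export
#' @examples
#' panel <- default_trait_panel()
#' table(panel$block)
default_trait_panel <- function() {
  mk <- function(prefix, n, stages, bilateral, block, lambda) {
    data.frame(
      trait_id = sprintf("%s%02d", prefix, seq_len(n)),
      n_stages = as.integer(stages),
      bilateral = bilateral,
      block = block,
      lambda = lambda,
      stringsAsFactors = FALSE
    )
  }
  panel <- rbind(
    # midline suture segments: binary, weak late-adult signal
    mk("SU", 9, 2, FALSE, "sutures", 0.6),
    # vertebral development/degeneration: 3-stage, strong signal
    mk("VX", 16, 3, FALSE, "axial", 2.2),
    # limb joint + entheseal degeneration: binary, mixed signal
    mk("AP", 23, 2, TRUE, "appendicular", rep(c(0.9, 1.8), length.out = 23)),
    mk("CL", 2, 3, TRUE, "clavicle", 2.0),
    # first rib costal face (3-stage) and tubercle (binary)
    mk("RB", 2, c(3, 2), FALSE, "first_rib", 1.9),
    mk("PS", 3, 3, TRUE, "pubic_symphysis", 1.6),
    # iliac/sacral auricular texture+margin (bilateral, 3-stage),
    # S1 body surface (3-stage) and S1-S2 fusion (binary), unilateral
    rbind(mk("SI", 4, 3, TRUE, "sacroiliac", 1.7),
          within(mk("SX", 2, c(3, 2), FALSE, "sacroiliac", 1.7), {
            trait_id <- c("SI05", "SI06")
          })),
    mk("AC", 3, 3, TRUE, "acetabulum", 2.0)
  )
  rownames(panel) <- NULL
  trait_schema(panel)
}

#' Resolve a trait preset to trait ids
#'
#' Named presets mirror the anatomical-block experiments of multifactorial
#' age estimation: each block name selects its traits; `"standard"`
#' selects the classical age indicators (clavicle, first rib, pubic
#' symphysis, sacroiliac complex, acetabulum); `"degenerative"` selects
#' the axial + appendicular degenerative traits; `"all"` selects
#' everything.
#'
#' @param preset a preset name or a character vector of trait ids.
#' @param schema a `trait_schema`.
#' @return Character vector of trait ids.
#' @export
resolve_preset <- function(preset, schema) {
  stopifnot(inherits(schema, "trait_schema"))
  if (length(preset) > 1L || all(preset %in% schema$trait_id)) {
    bad <- setdiff(preset, schema$trait_id)
    if (length(bad)) stop("unknown trait id(s): ", paste(bad, collapse = ", "))
    return(preset)
  }
  presets <- c(as.list(setNames(skeletal_blocks(), skeletal_blocks())),
               list(standard = c("clavicle", "first_rib", "pubic_symphysis",
                                 "sacroiliac", "acetabulum"),
                    degenerative = c("axial", "appendicular"),
                    all = skeletal_blocks()))
  if (!preset %in% names(presets)) {
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  }
  schema$trait_id[schema$block %in% presets[[preset]]]
}
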