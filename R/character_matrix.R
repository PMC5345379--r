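#' @useDynLib morphoclade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cells are stored as integer bitmasks over states: bit s (value 2^s) set iff
# state s is in the cell's state-set. Missing data is the full set 2^k - 1.
# This representation makes Fitch operations and likelihood leaf partials
# direct, and polymorphism a first-class citizen.

#' Construct per-character metadata
#'
#' One row per character, in the 1-based numbering used throughout (the
#' user-facing character numbers of a morphological matrix).
#'
#' @param k integer vector of state counts (states are `0..k-1`).
#' @param kind `"qualitative"` or `"quantitative"`, recycled.
#' @param ordered logical, recycled; ordered multistate characters change
#'   through adjacent states (likelihood) and cost `|i-j|` steps (parsimony).
#' @param included logical, recycled; excluded characters are retained in the
#'   matrix but skipped by all analyses.
#' @param label optional character labels.
#' @return a `data.frame` with columns `index`, `kind`, `ordered`, `k`,
#'   `included`, `label`.
#' @export
character_meta <- function(k, kind = "qualitative", ordered = FALSE,
                           included = TRUE, label = NA_character_) {
  n <- length(k)
  stopifnot(n >= 0, all(k >= 1))
  data.frame(
    index = seq_len(n),
    kind = rep_len(as.character(kind), n),
    ordered = rep_len(as.logical(ordered), n),
    k = as.integer(k),
    included = rep_len(as.logical(included), n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
}

#' Construct a character matrix
#'
#' The central container: taxa by characters, each cell a non-empty state-set
#' (singleton for an ordinary observation, a larger set for polymorphism, the
#' full set for missing data).
#'
#' @param cells either an integer matrix of state bitmasks (bit `s` set iff
#'   state `s` present) or a character matrix of cell strings such as `"0"`,
#'   `"(01)"`, `"?"`.
#' @param taxa taxon labels (unique); defaults to rownames of `cells`.
#' @param meta per-character metadata from [character_meta()]; state counts
#'   default to the largest state observed per column plus one.
#' @return an object of class `char_matrix` with elements `taxa`, `cells`
#'   (bitmask matrix), `meta`.
#' @export
character_matrix <- function(cells, taxa = rownames(cells), meta = NULL) {
  if (is.character(cells))
    cells <- .parse_cell_strings(cells, if (!is.null(meta)) meta$k)
  storage.mode(cells) <- "integer"
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(cells)))
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  if (length(taxa) != nrow(cells)) stop("taxa length must match rows of cells")
  nchar_ <- ncol(cells)
  if (is.null(meta)) {
    k_obs <- vapply(seq_len(nchar_), function(j) .mask_max_state(cells[, j]) + 1L, 1L)
    meta <- character_meta(pmax(k_obs, 1L))
  }
  if (nrow(meta) != nchar_) stop("meta must have one row per character")
  obj <- structure(list(taxa = as.character(taxa), cells = cells, meta = meta),
                   class = "char_matrix")
  validate_char_matrix(obj)
  obj
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (%d included)\n",
              length(x$taxa), nrow(x$meta), sum(x$meta$included)))
  invisible(x)
}

#' Validate a character matrix
#'
#' Checks the container invariants: unique taxa, rectangular cells, and every
#' cell a non-empty subset of `{0..k-1}` for its character.
#'
#' @param x a `char_matrix`.
#' @return `x`, invisibly; errors describe the offending taxon/character.
#' @export
validate_char_matrix <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  if (anyDuplicated(x$taxa)) stop("taxon labels must be unique")
  if (nrow(x$cells) != length(x$taxa)) stop("cells/taxa dimension mismatch")
  if (ncol(x$cells) != nrow(x$meta)) stop("cells/meta dimension mismatch")
  for (j in seq_len(ncol(x$cells))) {
    k <- x$meta$k[j]
    full <- bitwShiftL(1L, k) - 1L
    col <- x$cells[, j]
    if (any(col <= 0L))
      stop(sprintf("character %d: empty state-set for taxon '%s'",
                   j, x$taxa[which(col <= 0L)[1]]))
    bad <- bitwAnd(col, bitwNot(full)) != 0L
    if (any(bad))
      stop(sprintf("character %d: state outside 0..%d for taxon '%s'",
                   j, k - 1L, x$taxa[which(bad)[1]]))
  }
  invisible(x)
}

#' Mark characters as excluded from analysis
#'
#' Excluded characters keep their column and 1-based number (so reports stay
#' aligned with the published character list) but contribute nothing to
#' likelihoods, parsimony lengths or counts. Idempotent.
#'
#' @param matrix a `char_matrix`.
#' @param excluded integer vector of 1-based character indices.
#' @return the matrix with `meta$included` updated.
#' @export
apply_exclusions <- function(matrix, excluded) {
  stopifnot(inherits(matrix, "char_matrix"))
  excluded <- as.integer(excluded)
  if (length(excluded) == 0) return(matrix)
  bad <- setdiff(excluded, matrix$meta$index)
  if (length(bad) > 0)
    stop(sprintf("unknown character index: %s", paste(bad, collapse = ", ")))
  matrix$meta$included[matrix$meta$index %in% excluded] <- FALSE
  matrix
}

#' Drop excluded columns outright
#'
#' Convenience for equivalence checks: returns a matrix containing only the
#' included characters, renumbered contiguously.
#'
#' @param matrix a `char_matrix`.
#' @return a `char_matrix` of the included characters only.
#' @export
included_only <- function(matrix) {
  keep <- which(matrix$meta$included)
  meta <- matrix$meta[keep, , drop = FALSE]
  meta$index <- seq_along(keep)
  rownames(meta) <- NULL
  character_matrix(matrix$cells[, keep, drop = FALSE], matrix$taxa, meta)
}

# ---- cell/bitmask helpers ----------------------------------------------------

.mask_from_states <- function(states) {
  as.integer(sum(bitwShiftL(1L, unique(as.integer(states)))))
}

.states_from_mask <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L) - 1L
}

.mask_max_state <- function(masks) {
  m <- max(masks)
  if (m <= 0L) return(-1L)
  as.integer(floor(log2(m + 0.5)))
}

.mask_is_singleton <- function(mask) {
  mask > 0L & bitwAnd(mask, mask - 1L) == 0L
}

.full_mask <- function(k) bitwShiftL(1L, as.integer(k)) - 1L

# Parse a character matrix of cell strings ("0", "(01)", "{02}", "?", "-").
# Missing markers become the full state-set; k per column is taken from
# `k_declared` when supplied, else from the largest observed state.
.parse_cell_strings <- function(cells, k_declared = NULL) {
  out <- matrix(0L, nrow(cells), ncol(cells), dimnames = dimnames(cells))
  for (j in seq_len(ncol(cells))) {
    col <- cells[, j]
    out[, j] <- vapply(col, .parse_one_cell, 0L, USE.NAMES = FALSE)
  }
  kmax <- vapply(seq_len(ncol(out)), function(j) {
    known <- out[, j][out[, j] > 0L]
    if (length(known) == 0L) 1L else .mask_max_state(known) + 1L
  }, 1L)
  if (!is.null(k_declared)) kmax <- pmax(kmax, as.integer(k_declared))
  for (j in seq_len(ncol(out))) {
    miss <- out[, j] == 0L
    out[miss, j] <- .full_mask(max(kmax[j], 1L))
  }
  out
}

.parse_one_cell <- function(s) {
  s <- trimws(s)
  if (s %in% c("?", "-", "")) return(0L)  # sentinel: fill with full set later
  digits <- strsplit(gsub("[(){}\\s]", "", s), "")[[1]]
  if (length(digits) == 0L || !all(digits %in% as.character(0:9)))
    stop(sprintf("cannot parse cell '%s'", s))
  .mask_from_states(as.integer(digits))
}

# Render a bitmask cell back to its NEXUS token.
.cell_to_token <- function(mask, k) {
  if (mask == .full_mask(k) && k > 1L) return("?")
  st <- .states_from_mask(mask)
  if (length(st) == 1L) as.character(st) else
    paste0("(", paste(st, collapse = ""), ")")
}
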