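# Character coding: across-species-median binarization of quantitative
# characters and majority coding of intraspecifically polymorphic qualitative
# observations.

#' Binarize a quantitative character at the across-species median
#'
#' Each species' mean measurement (a ratio or angle) is compared with the
#' median of the non-missing values: values above the median become state 1,
#' values at or below it state 0. Missing values stay missing. For an even
#' number of values the median is the midpoint of the central order
#' statistics. A constant column yields all-0 with a warning.
#'
#' @param values numeric vector, one value per taxon; `NA` = missing.
#' @return integer vector of states in `{0, 1}` with `NA` preserved.
#' @export
binarize_quantitative <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0) stop("all values missing: cannot binarize")
  med <- stats::median(obs)
  if (all(obs == obs[1]))
    warning("constant quantitative character: all taxa coded 0")
  out <- ifelse(values > med, 1L, 0L)
  out[is.na(values)] <- NA_integer_
  out
}

#' Majority-code a multiset of observed states
#'
#' Returns the modal state of the observations for one taxon and character;
#' an exact tie is retained as a polymorphic state-set rather than resolved
#' arbitrarily.
#'
#' @param observations integer vector of observed states (with repeats).
#' @return sorted integer vector: the modal state, or the tied states.
#' @export
majority_code <- function(observations) {
  if (length(observations) == 0) stop("empty observation multiset")
  tab <- table(observations)
  modal <- names(tab)[tab == max(tab)]
  sort(as.integer(modal))
}

#' Assemble the analysis matrix from raw observations
#'
#' Combines majority-coded qualitative observations with median-binarized
#' quantitative values into one [character_matrix()], following the given
#' metadata's column order (quantitative columns become binary, `k = 2`).
#'
#' @param qual_observations a list, one element per qualitative character (in
#'   metadata order), each itself a named list mapping taxon label to the
#'   integer vector of raw observed states for that species.
#' @param quant_table a data.frame of per-species mean measurements: first
#'   column `taxon`, then one numeric column per quantitative character in
#'   metadata order (see [read_quantitative_table()]).
#' @param meta [character_meta()] describing all characters; `kind` decides
#'   which input feeds each column.
#' @return a list with elements `matrix` (the coded [character_matrix()]) and
#'   `report` (per-character data.frame: `index`, `k`, `constant`,
#'   `n_missing`), flagging constant columns.
#' @export
code_matrix <- function(qual_observations, quant_table, meta) {
  taxa_q <- quant_table$taxon
  taxa_all <- unique(unlist(c(list(taxa_q), lapply(qual_observations, names))))
  if (length(taxa_all) == 0) stop("no taxa in coding inputs")
  for (obs in qual_observations) {
    extra <- setdiff(names(obs), taxa_all)
    if (length(extra) > 0)
      stop(sprintf("taxon '%s' present in qualitative input only", extra[1]))
  }
  missing_q <- setdiff(taxa_all, taxa_q)
  if (length(missing_q) > 0 && sum(meta$kind == "quantitative") > 0)
    stop(sprintf("taxon '%s' absent from quantitative table", missing_q[1]))

  n <- length(taxa_all)
  nchar_ <- nrow(meta)
  cells <- matrix(0L, n, nchar_)
  iq <- 0L  # cursor into quantitative columns
  il <- 0L  # cursor into qualitative observation list
  for (j in seq_len(nchar_)) {
    if (meta$kind[j] == "quantitative") {
      iq <- iq + 1L
      vals <- quant_table[[iq + 1L]][match(taxa_all, taxa_q)]
      st <- binarize_quantitative(vals)
      cells[, j] <- ifelse(is.na(st), .full_mask(2L), bitwShiftL(1L, st))
    } else {
      il <- il + 1L
      obs <- qual_observations[[il]]
      k <- meta$k[j]
      cells[, j] <- vapply(taxa_all, function(tx) {
        o <- obs[[tx]]
        if (is.null(o) || length(o) == 0) .full_mask(k)
        else .mask_from_states(majority_code(o))
      }, 0L, USE.NAMES = FALSE)
    }
  }
  meta$k[meta$kind == "quantitative"] <- 2L
  m <- character_matrix(cells, taxa_all, meta)
  report <- data.frame(
    index = meta$index,
    k = meta$k,
    constant = vapply(seq_len(nchar_), function(j) {
      col <- cells[, j]
      sing <- col[.mask_is_singleton(col)]
      length(unique(sing)) <= 1L
    }, TRUE),
    n_missing = vapply(seq_len(nchar_), function(j) {
      sum(cells[, j] == .full_mask(meta$k[j]))
    }, 0L)
  )
  list(matrix = m, report = report)
}

#' Read a quantitative measurement table from TSV
#'
#' Expected layout: a `taxon` column followed by one numeric column per
#' quantitative character; empty cells or `NA` are missing.
#'
#' @param path TSV path.
#' @return a data.frame with `taxon` first.
#' @export
read_quantitative_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "taxon") names(df)[1] <- "taxon"
  df
}

#' Write a quantitative measurement table to TSV
#' @param table data.frame as in [read_quantitative_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quantitative_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
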