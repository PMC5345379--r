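# NEXUS I/O for morphological ("standard" datatype) matrices, in the
# MrBayes-compatible subset: FORMAT symbols="0123456789", missing=?, gap=-
# (gap read as missing), polymorphism as parenthesized or braced state groups,
# ordering and exclusion metadata in an ASSUMPTIONS block (ctype/exset).

#' Read a morphological character matrix from NEXUS
#'
#' Parses a DATA or CHARACTERS block with a MATRIX command, one taxon per row.
#' Polymorphic cells like `(01)` become state-sets; `?` and `-` become the
#' full state-set of the character. An ASSUMPTIONS block's `ctype ord:` and
#' `exset` commands populate the `ordered` and `included` metadata flags.
#'
#' @param path path to a NEXUS file.
#' @return a [character_matrix()].
#' @export
read_nexus <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- .strip_nexus_comments(txt)
  if (!grepl("^\\s*#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")

  blocks <- .nexus_blocks(txt)
  data_block <- blocks[["data"]]
  if (is.null(data_block)) data_block <- blocks[["characters"]]
  if (is.null(data_block)) stop("no DATA or CHARACTERS block found")

  cmds <- .nexus_commands(data_block)
  dims <- .nexus_find_command(cmds, "dimensions")
  ntax <- .nexus_kv(dims, "ntax")
  nchar_ <- .nexus_kv(dims, "nchar")
  if (is.na(nchar_)) stop("DIMENSIONS must declare NCHAR")
  fmt <- .nexus_find_command(cmds, "format")
  symbols <- if (!is.null(fmt)) .nexus_kv_str(fmt, "symbols") else NULL
  symbols <- if (is.null(symbols) || is.na(symbols)) as.character(0:9) else
    strsplit(gsub("\\s", "", symbols), "")[[1]]

  mat_cmd <- .nexus_find_command(cmds, "matrix")
  if (is.null(mat_cmd)) stop("no MATRIX command in data block")
  rows <- .parse_nexus_matrix(mat_cmd, nchar_, symbols)
  if (!is.na(ntax) && length(rows$taxa) != ntax)
    warning(sprintf("NTAX=%d but %d taxa parsed", ntax, length(rows$taxa)))

  meta <- character_meta(pmax(rows$k, 1L))
  assume <- blocks[["assumptions"]]
  if (!is.null(assume)) {
    acmds <- .nexus_commands(assume)
    for (cmd in acmds) {
      word <- tolower(sub("^\\s*(\\S+).*$", "\\1", cmd))
      if (word == "ctype") {
        body <- sub("^\\s*\\S+\\s*", "", cmd)
        parts <- strsplit(body, ",")[[1]]
        for (p in parts) {
          bits <- strsplit(p, ":")[[1]]
          if (length(bits) != 2) next
          type <- tolower(trimws(bits[1]))
          idx <- .parse_index_list(bits[2], nchar_)
          if (type %in% c("ord", "ordered")) meta$ordered[idx] <- TRUE
        }
      } else if (word == "exset") {
        body <- sub("^\\s*\\S+\\s*", "", cmd)
        body <- sub("^.*=", "", body)
        idx <- .parse_index_list(body, nchar_)
        meta$included[idx] <- FALSE
      }
    }
  }
  character_matrix(rows$cells, rows$taxa, meta)
}

#' Write a character matrix to NEXUS
#'
#' Emits a DATA block plus an ASSUMPTIONS block carrying ordering (`ctype
#' ord:`) and exclusion (`exset`) metadata, so that [read_nexus()] recovers an
#' identical matrix.
#'
#' @param matrix a [character_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(matrix, path) {
  validate_char_matrix(matrix)
  ntax <- length(matrix$taxa)
  nchar_ <- nrow(matrix$meta)
  kmax <- if (nchar_ > 0) max(matrix$meta$k) else 2L
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", ntax, nchar_),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(seq_len(max(kmax, 2L)) - 1L, collapse = "")),
    "  MATRIX"
  )
  # '?' is only safe when the column's k is recoverable from the other cells;
  # otherwise a full-set cell is written as an explicit state group.
  safe_q <- vapply(seq_len(nchar_), function(j) {
    k <- matrix$meta$k[j]
    col <- matrix$cells[, j]
    sub <- col[col != .full_mask(k)]
    length(sub) > 0 && .mask_max_state(sub) + 1L == k
  }, TRUE)
  labels <- gsub("[^A-Za-z0-9_.]", "_", matrix$taxa)
  width <- max(nchar(labels), 0) + 2L
  for (i in seq_len(ntax)) {
    toks <- vapply(seq_len(nchar_), function(j) {
      k <- matrix$meta$k[j]
      mask <- matrix$cells[i, j]
      if (mask == .full_mask(k) && !safe_q[j] && k > 1L)
        paste0("(", paste(.states_from_mask(mask), collapse = ""), ")")
      else .cell_to_token(mask, k)
    }, "")
    lines <- c(lines, paste0("  ", formatC(labels[i], width = -width), paste(toks, collapse = "")))
  }
  lines <- c(lines, "  ;", "END;")
  ord <- matrix$meta$index[matrix$meta$ordered]
  excl <- matrix$meta$index[!matrix$meta$included]
  if (length(ord) > 0 || length(excl) > 0) {
    lines <- c(lines, "BEGIN ASSUMPTIONS;")
    if (length(ord) > 0)
      lines <- c(lines, sprintf("  CTYPE ORD: %s;", paste(ord, collapse = " ")))
    if (length(excl) > 0)
      lines <- c(lines, sprintf("  EXSET * excluded = %s;", paste(excl, collapse = " ")))
    lines <- c(lines, "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- internals ---------------------------------------------------------------

.strip_nexus_comments <- function(txt) {
  gsub("\\[[^]]*\\]", " ", txt)
}

# Split text into named blocks: BEGIN <name>; ... END;
.nexus_blocks <- function(txt) {
  m <- gregexpr("(?is)begin\\s+(\\w+)\\s*;(.*?)end\\s*;", txt, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  out <- list()
  if (starts[1] == -1) return(out)
  for (i in seq_along(starts)) {
    blk <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    name <- tolower(sub("(?is)^begin\\s+(\\w+).*$", "\\1", blk, perl = TRUE))
    body <- sub("(?is)^begin\\s+\\w+\\s*;", "", blk, perl = TRUE)
    body <- sub("(?is)end\\s*;\\s*$", "", body, perl = TRUE)
    out[[name]] <- body
  }
  out
}

# Split a block body into ';'-terminated commands.
.nexus_commands <- function(body) {
  cmds <- strsplit(body, ";", fixed = TRUE)[[1]]
  cmds <- trimws(cmds)
  cmds[nzchar(cmds)]
}

.nexus_find_command <- function(cmds, name) {
  hit <- grep(paste0("(?i)^", name, "\\b"), cmds, perl = TRUE)
  if (length(hit) == 0) return(NULL)
  cmds[[hit[1]]]
}

.nexus_kv <- function(cmd, key) {
  if (is.null(cmd)) return(NA_integer_)
  m <- regmatches(cmd, regexpr(paste0("(?i)", key, "\\s*=\\s*\\d+"), cmd, perl = TRUE))
  if (length(m) == 0) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m))
}

.nexus_kv_str <- function(cmd, key) {
  m <- regmatches(cmd, regexpr(paste0("(?i)", key, "\\s*=\\s*\"[^\"]*\""), cmd, perl = TRUE))
  if (length(m) == 0) return(NA_character_)
  sub(".*\"([^\"]*)\".*", "\\1", m)
}

# Parse "1 4 9-12 20" (1-based, with ranges) into an index vector.
.parse_index_list <- function(s, nchar_) {
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  idx <- integer(0)
  for (t in toks) {
    if (grepl("^\\d+$", t)) idx <- c(idx, as.integer(t))
    else if (grepl("^\\d+-\\d+$", t)) {
      ab <- as.integer(strsplit(t, "-")[[1]])
      idx <- c(idx, seq(ab[1], ab[2]))
    } else if (tolower(t) == "all") idx <- c(idx, seq_len(nchar_))
    else stop(sprintf("cannot parse character index '%s'", t))
  }
  bad <- idx[idx < 1 | idx > nchar_]
  if (length(bad) > 0)
    stop(sprintf("character index out of range: %s", paste(bad, collapse = ", ")))
  unique(idx)
}

# Parse the MATRIX command body: one taxon per line.
.parse_nexus_matrix <- function(mat_cmd, nchar_, symbols) {
  body <- sub("(?i)^matrix", "", mat_cmd, perl = TRUE)
  rows <- strsplit(body, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  taxa <- character(0)
  mask_rows <- list()
  sym_states <- suppressWarnings(as.integer(symbols))
  for (row in rows) {
    if (grepl("^'", row)) {
      label <- sub("^'([^']*)'.*$", "\\1", row)
      rest <- sub("^'[^']*'", "", row)
    } else {
      label <- sub("^(\\S+).*$", "\\1", row)
      rest <- sub("^\\S+", "", row)
    }
    rest <- gsub("\\s", "", rest)
    masks <- .parse_cell_run(rest, label, symbols, sym_states)
    if (length(masks) != nchar_)
      stop(sprintf("taxon '%s': %d characters found, NCHAR=%d",
                   label, length(masks), nchar_))
    taxa <- c(taxa, label)
    mask_rows[[length(mask_rows) + 1L]] <- masks
  }
  cells <- matrix(unlist(mask_rows), nrow = length(taxa), ncol = nchar_,
                  byrow = TRUE)
  # missing sentinel (0) -> full set per column
  k <- vapply(seq_len(nchar_), function(j) {
    known <- cells[, j][cells[, j] > 0L]
    if (length(known) == 0L) 1L else .mask_max_state(known) + 1L
  }, 1L)
  for (j in seq_len(nchar_)) {
    miss <- cells[, j] == 0L
    cells[miss, j] <- .full_mask(k[j])
  }
  dimnames(cells) <- NULL
  list(taxa = taxa, cells = cells, k = k)
}

# One taxon's concatenated cell string -> integer masks (0 = missing sentinel).
.parse_cell_run <- function(s, label, symbols, sym_states) {
  chars <- strsplit(s, "")[[1]]
  masks <- integer(0)
  i <- 1L
  pos <- 0L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    pos <- pos + 1L
    if (ch %in% c("?", "-")) {
      masks <- c(masks, 0L)
      i <- i + 1L
    } else if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      j <- i + 1L
      grp <- integer(0)
      while (j <= n && chars[j] != close) {
        st <- .symbol_state(chars[j], symbols, sym_states, label, pos)
        grp <- c(grp, st)
        j <- j + 1L
      }
      if (j > n) stop(sprintf("taxon '%s': unterminated state group", label))
      if (length(grp) == 0) stop(sprintf("taxon '%s': empty state group", label))
      masks <- c(masks, .mask_from_states(grp))
      i <- j + 1L
    } else {
      st <- .symbol_state(ch, symbols, sym_states, label, pos)
      masks <- c(masks, bitwShiftL(1L, st))
      i <- i + 1L
    }
  }
  masks
}

.symbol_state <- function(ch, symbols, sym_states, label, pos) {
  hit <- match(ch, symbols)
  if (is.na(hit))
    stop(sprintf("taxon '%s', character %d: symbol '%s' not in declared symbols",
                 label, pos, ch))
  st <- sym_states[hit]
  if (is.na(st)) st <- hit - 1L
  st
}
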