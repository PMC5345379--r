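# Bipartition (split) machinery. A split is stored canonically as a logical
# vector over a fixed, documented taxon ordering (the matrix row order),
# flipped so the side containing the first taxon is FALSE; its key is the
# corresponding 0/1 string. Only nontrivial splits (both sides >= 2) are kept.

# All nontrivial splits of an (unrooted or rooted) binary-ish tree, with the
# branch length subtending each. Returns list(keys, lengths, sides).
.tree_splits <- function(tree, taxa) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  tip_col <- match(tree$tip.label, taxa)
  if (anyNA(tip_col)) stop("tree tips not a subset of the taxon ordering")
  ntaxa <- length(taxa)
  nnodes <- ntip + tree$Nnode
  below <- matrix(FALSE, nnodes, ntaxa)
  below[cbind(seq_len(ntip), tip_col)] <- TRUE
  edge <- tree$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; c <- edge[e, 2]
    below[p, ] <- below[p, ] | below[c, ]
  }
  keys <- character(0); lens <- numeric(0); sides <- list()
  present <- tip_col  # columns actually present in this tree
  for (e in seq_len(nrow(edge))) {
    c <- edge[e, 2]
    if (c <= ntip) next
    side <- below[c, ]
    sz <- sum(side)
    if (sz < 2 || sz > ntip - 2) next
    side_n <- .canonical_side(side, present)
    keys <- c(keys, .split_key(side_n, present))
    lens <- c(lens, if (is.null(tree$edge.length)) NA_real_ else tree$edge.length[e])
    sides[[length(sides) + 1L]] <- side_n
  }
  list(keys = keys, lengths = lens, sides = sides)
}

# Flip so that the lowest-index present taxon is on the FALSE side.
.canonical_side <- function(side, present) {
  anchor <- min(present)
  if (side[anchor]) {
    flipped <- !side
    flipped[-present] <- FALSE
    flipped
  } else side
}

.split_key <- function(side, present) {
  v <- integer(length(side))
  v[side] <- 1L
  v[-present] <- 9L  # absent taxa marked so reduced-tip-set keys never collide
  paste(v, collapse = "")
}

# Encode a taxon subset as a canonical key relative to `taxa` ordering,
# restricted to the present tips.
.set_key <- function(taxon_set, taxa, present_labels = taxa) {
  present <- match(present_labels, taxa)
  side <- taxa %in% taxon_set
  side[-present] <- FALSE
  .split_key(.canonical_side(side, present), present)
}

# Count splits over a list of trees: key -> list(count, sum of branch lengths).
.split_counts <- function(trees, taxa) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  sides <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in trees) {
    sp <- .tree_splits(tr, taxa)
    for (i in seq_along(sp$keys)) {
      k <- sp$keys[i]
      cur <- get0(k, envir = env, ifnotfound = c(0, 0))
      len <- sp$lengths[i]
      cur <- c(cur[1] + 1, cur[2] + if (is.na(len)) 0 else len)
      assign(k, cur, envir = env)
      if (is.null(get0(k, envir = sides))) assign(k, sp$sides[[i]], envir = sides)
    }
  }
  keys <- ls(env)
  counts <- vapply(keys, function(k) get(k, envir = env)[1], 0)
  lensum <- vapply(keys, function(k) get(k, envir = env)[2], 0)
  side_list <- lapply(keys, function(k) get(k, envir = sides))
  list(keys = keys, counts = counts, lensum = lensum, sides = side_list)
}

#' Split frequency table of a tree sample
#'
#' Frequencies of nontrivial bipartitions in a (post-burnin) tree sample,
#' relative to a fixed taxon ordering.
#'
#' @param trees a `multiPhylo`/list of trees, or a [tree_sample()].
#' @param taxa reference taxon ordering (defaults to the first tree's tips).
#' @return data.frame with `key`, `freq`, `count`, `mean_length` plus
#'   attribute `n` (sample size) and `sides` (list of logical taxon masks).
#' @export
split_table <- function(trees, taxa = NULL) {
  if (inherits(trees, "tree_sample")) trees <- trees$trees
  if (length(trees) == 0) stop("empty tree sample")
  if (is.null(taxa)) taxa <- sort(trees[[1]]$tip.label)
  sc <- .split_counts(trees, taxa)
  df <- data.frame(key = sc$keys,
                   freq = sc$counts / length(trees),
                   count = sc$counts,
                   mean_length = ifelse(sc$counts > 0, sc$lensum / sc$counts, NA),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$freq, df$key), ]
  rownames(df) <- NULL
  attr(df, "n") <- length(trees)
  attr(df, "sides") <- sc$sides[match(df$key, sc$keys)]
  attr(df, "taxa") <- taxa
  df
}

# Build an ape tree from a set of pairwise-compatible splits (logical sides
# over `taxa`, all canonical: anchor taxon on FALSE side). Optional labels and
# branch lengths per split; tip edge lengths optional vector.
.tree_from_splits <- function(sides, taxa, labels = NULL, lengths = NULL,
                              tip_lengths = NULL) {
  n <- length(taxa)
  clusters <- lapply(sides, which)  # clusters exclude the anchor taxon
  ord <- order(-vapply(clusters, length, 0L))
  clusters <- clusters[ord]
  labels <- if (!is.null(labels)) labels[ord]
  lengths <- if (!is.null(lengths)) lengths[ord]
  # parent of each cluster = smallest strictly-containing cluster (or root)
  m <- length(clusters)
  root_id <- n + 1L
  node_id <- if (m > 0) n + 1L + seq_len(m) else integer(0)
  parent <- rep(root_id, m)
  if (m > 1) for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      # clusters sorted by decreasing size: j precedes i, may contain i
      if (all(clusters[[i]] %in% clusters[[j]])) parent[i] <- node_id[j]
    }
  }
  tip_parent <- rep(root_id, n)
  for (i in seq_len(m)) tip_parent[clusters[[i]]] <- node_id[i]
  edge <- rbind(cbind(parent, node_id),
                cbind(tip_parent, seq_len(n)))
  edge <- matrix(as.integer(edge), ncol = 2, dimnames = NULL)
  elen <- c(if (is.null(lengths)) rep(NA_real_, m) else lengths,
            if (is.null(tip_lengths)) rep(NA_real_, n) else tip_lengths)
  tr <- list(edge = edge, tip.label = taxa, Nnode = m + 1L,
             node.label = c("", if (is.null(labels)) rep("", m) else as.character(labels)))
  if (!all(is.na(elen))) tr$edge.length <- elen
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr <- stats::reorder(tr, "cladewise")
  tr
}
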