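# Maximum parsimony: Fitch (unordered) and Sankoff (ordered, |i-j| costs)
# scoring on state-set bitmasks, heuristic search by random stepwise addition
# with pool-closure NNI swapping, exhaustive enumeration for small taxon sets,
# strict consensus, nonparametric bootstrap, and Bremer decay via
# reverse-constraint search.
#
# Internally trees are unrooted and handled as plain integer edge matrices in
# postorder (tips 1..n matching a taxon ordering, internals above); `phylo`
# objects appear only at the public surface.

# ---- scoring -----------------------------------------------------------------

# Fitch step counts for unordered characters, vectorized over columns.
# edges: postorder (parent, child) matrix; masks: ntip x nchar bitmasks.
.fitch_steps <- function(edges, ntip, masks, weights = NULL) {
  nchar_ <- ncol(masks)
  if (nchar_ == 0) return(0)
  if (is.null(weights)) weights <- rep(1, nchar_)
  nnodes <- max(edges)
  state <- matrix(0L, nnodes, nchar_)
  state[seq_len(ntip), ] <- masks
  seen <- logical(nnodes)
  seen[seq_len(ntip)] <- TRUE
  steps <- numeric(nchar_)
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; c <- edges[e, 2]
    if (!seen[p]) {
      state[p, ] <- state[c, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(state[p, ], state[c, ])
      hit <- inter == 0L
      if (any(hit)) {
        inter[hit] <- bitwOr(state[p, hit], state[c, hit])
        steps[hit] <- steps[hit] + weights[hit]
      }
      state[p, ] <- inter
    }
  }
  sum(steps)
}

# Sankoff step counts under linear (ordered) costs |i-j|, vectorized over the
# columns of one k-group.
.sankoff_steps <- function(edges, ntip, masks, k, weights = NULL) {
  nchar_ <- ncol(masks)
  if (nchar_ == 0) return(0)
  if (is.null(weights)) weights <- rep(1, nchar_)
  nnodes <- max(edges)
  BIG <- 1e9
  cost <- array(0, dim = c(k, nchar_, nnodes))
  for (i in seq_len(ntip)) {
    m <- matrix(BIG, k, nchar_)
    for (s in seq_len(k) - 1L) {
      inset <- bitwAnd(masks[i, ], bitwShiftL(1L, s)) != 0L
      m[s + 1L, inset] <- 0
    }
    cost[, , i] <- m
  }
  seen <- logical(nnodes)
  seen[seq_len(ntip)] <- TRUE
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; c <- edges[e, 2]
    cc <- matrix(cost[, , c], k, nchar_)
    tc <- matrix(BIG, k, nchar_)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        cand <- cc[j, ] + abs(i - j)
        tc[i, ] <- pmin(tc[i, ], cand)
      }
    }
    if (!seen[p]) {
      cost[, , p] <- tc
      seen[p] <- TRUE
    } else {
      cost[, , p] <- matrix(cost[, , p], k, nchar_) + tc
    }
  }
  root <- edges[nrow(edges), 1]
  rc <- matrix(cost[, , root], k, nchar_)
  sum(apply(rc, 2, min) * weights)
}

# Total weighted parsimony length on a raw postorder edge matrix.
.length_edges <- function(edges, ntip, matrix, weights = NULL, char_idx = NULL) {
  if (is.null(char_idx)) char_idx <- which(matrix$meta$included)
  if (length(char_idx) == 0) return(0)
  if (is.null(weights)) weights <- rep(1, length(char_idx))
  ord <- matrix$meta$ordered[char_idx] & matrix$meta$k[char_idx] > 2
  total <- 0
  if (any(!ord)) {
    total <- total + .fitch_steps(edges, ntip,
                                  matrix$cells[, char_idx[!ord], drop = FALSE],
                                  weights[!ord])
  }
  if (any(ord)) {
    ks <- matrix$meta$k[char_idx[ord]]
    for (kk in unique(ks)) {
      sel <- char_idx[ord][ks == kk]
      wsel <- weights[ord][ks == kk]
      total <- total + .sankoff_steps(edges, ntip,
                                      matrix$cells[, sel, drop = FALSE], kk, wsel)
    }
  }
  total
}

#' Parsimony steps of one character on a tree
#'
#' Unordered characters use Fitch counting; ordered characters use Sankoff
#' dynamic programming with cost `|i - j|`. Ambiguity sets are optional leaf
#' assignments minimized over; a missing cell (full set) never forces a step.
#'
#' @param tree `ape::phylo` whose tips match the column names.
#' @param column integer bitmask vector named by taxon, or single-column
#'   [character_matrix()].
#' @param meta single-row [character_meta()] when `column` is bare.
#' @return integer step count.
#' @export
character_length <- function(tree, column, meta = NULL) {
  if (inherits(column, "char_matrix")) m <- column
  else m <- character_matrix(matrix(as.integer(column), ncol = 1),
                             names(column), meta)
  tree_length(tree, m)
}

#' Parsimony length of a tree
#'
#' Sum of per-character minimum step counts over included characters.
#'
#' @param tree `ape::phylo` over the matrix taxa.
#' @param matrix a [character_matrix()].
#' @param weights optional per-included-character weights (used by the
#'   bootstrap; default all 1).
#' @return numeric length (integer-valued for unit weights).
#' @export
tree_length <- function(tree, matrix, weights = NULL) {
  pe <- .phylo_to_edges(tree, matrix$taxa)
  .length_edges(pe$edges, pe$ntip, matrix, weights)
}

#' Minimum conceivable steps of a character
#'
#' The number of steps the character needs on a best-case tree: for unordered
#' characters, (size of the smallest state set hitting every taxon's
#' state-set) minus one; for ordered characters, the length of the shortest
#' state interval hitting every state-set.
#'
#' @param column integer bitmask vector (one cell per taxon) or single-column
#'   [character_matrix()].
#' @param meta single-row [character_meta()] when `column` is bare.
#' @return integer minimum steps.
#' @export
min_steps <- function(column, meta = NULL) {
  if (inherits(column, "char_matrix")) {
    meta <- column$meta[1, , drop = FALSE]
    column <- column$cells[, 1]
  }
  if (is.null(meta)) meta <- character_meta(.mask_max_state(column) + 1L)[1, ]
  k <- meta$k
  masks <- as.integer(column)
  if (length(masks) == 0 || k == 1) return(0L)
  if (meta$ordered && k > 2) {
    best <- Inf
    for (a in seq_len(k) - 1L) for (b in a:(k - 1L)) {
      span <- .mask_from_states(a:b)
      if (all(bitwAnd(masks, span) != 0L)) best <- min(best, b - a)
    }
    return(as.integer(best))
  }
  # smallest hitting set over <= 2^k state subsets
  for (size in 1:k) {
    combs <- utils::combn(seq_len(k) - 1L, size, simplify = FALSE)
    for (ss in combs) {
      span <- .mask_from_states(ss)
      if (all(bitwAnd(masks, span) != 0L)) return(size - 1L)
    }
  }
  k - 1L
}

#' Ensemble consistency index
#'
#' `CI = sum(min_steps) / length` over included characters.
#'
#' @param matrix a [character_matrix()].
#' @param length realized tree length (steps).
#' @return CI in `(0, 1]`, or `NA` for zero length.
#' @export
consistency_index <- function(matrix, length) {
  inc <- which(matrix$meta$included)
  m <- sum(vapply(inc, function(j)
    min_steps(matrix$cells[, j], matrix$meta[j, , drop = FALSE]), 0L))
  if (length == 0) return(NA_real_)
  m / length
}

#' Count parsimony-informative characters
#'
#' An included character is parsimony-informative when at least two states
#' are each observed unambiguously (singleton state-set) in at least two
#' taxa.
#'
#' @param matrix a [character_matrix()].
#' @return integer count.
#' @export
parsimony_informative_count <- function(matrix) {
  inc <- which(matrix$meta$included)
  sum(vapply(inc, function(j) {
    col <- matrix$cells[, j]
    sing <- col[.mask_is_singleton(col)]
    sum(table(sing) >= 2) >= 2
  }, TRUE))
}

# ---- raw edge-matrix tree machinery -----------------------------------------

# Convert a phylo to (postorder edges, ntip) with tips renumbered to match
# the reference taxon ordering.
.phylo_to_edges <- function(tree, taxa) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  map <- match(tree$tip.label, taxa)
  if (anyNA(map)) stop("tree tips do not match matrix taxa")
  edges <- tree$edge
  # renumber: tip i -> map[i]; internal j -> length(taxa) + (j - ntip)
  renum <- function(x) ifelse(x <= ntip, map[x], x - ntip + length(taxa))
  list(edges = cbind(renum(edges[, 1]), renum(edges[, 2])),
       ntip = length(taxa))
}

# Orient an undirected edge matrix from `root`, returning postorder
# (parent, child) rows.
.postorder_edges <- function(und, root) {
  m <- nrow(und)
  adj <- split(c(und[, 2], und[, 1]), c(und[, 1], und[, 2]))
  out <- matrix(0L, m, 2)
  cnt <- 0L
  stack <- list(c(root, 0L))
  pre <- matrix(0L, m, 2)
  # iterative preorder
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]; par <- top[2]
    for (nb in adj[[as.character(node)]]) {
      if (nb != par) {
        cnt <- cnt + 1L
        pre[cnt, ] <- c(node, nb)
        stack[[length(stack) + 1L]] <- c(nb, node)
      }
    }
  }
  pre[rev(seq_len(m)), , drop = FALSE]
}

# Convert raw undirected edges (tips 1..ntip within `taxa`) to a phylo.
.edges_to_phylo <- function(und, ntip, tip_labels) {
  root <- und[which(und[, 1] > ntip | und[, 2] > ntip)[1], ]
  root <- root[root > ntip][1]
  if (is.na(root)) root <- und[1, 1]  # 2-taxon tree
  po <- .postorder_edges(und, root)
  nodes <- unique(c(po[, 1], po[, 2]))
  internals <- sort(nodes[nodes > ntip])
  # ape numbering: root gets ntip+1, others follow discovery order
  pre_nodes <- unique(c(root, po[rev(seq_len(nrow(po))), 2]))
  pre_int <- pre_nodes[pre_nodes > ntip]
  new_id <- integer(max(nodes))
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[pre_int] <- ntip + seq_along(pre_int)
  edge <- cbind(new_id[po[, 1]], new_id[po[, 2]])
  tr <- list(edge = matrix(as.integer(edge), ncol = 2),
             tip.label = tip_labels[seq_len(ntip)],
             Nnode = length(pre_int))
  class(tr) <- "phylo"
  attr(tr, "order") <- "postorder"
  tr
}

# All unrooted binary topologies on tips 1..n (raw undirected edges).
.all_topologies <- function(n) {
  if (n < 3) stop("need >= 3 taxa")
  base <- cbind(n + 1L, 1:3)
  trees <- list(list(edges = base, next_node = n + 2L))
  for (tip in 4:n) {
    if (tip > n) break
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        u <- tr$edges[e, 1]; v <- tr$edges[e, 2]
        w <- tr$next_node
        ed <- tr$edges[-e, , drop = FALSE]
        ed <- rbind(ed, c(u, w), c(w, v), c(w, tip))
        nxt[[length(nxt) + 1L]] <- list(edges = ed, next_node = w + 1L)
      }
    }
    trees <- nxt
  }
  lapply(trees, `[[`, "edges")
}

# Insert tip `tip` into undirected edge row e of `und`, using `new_node`.
.insert_tip_edges <- function(und, e, tip, new_node) {
  u <- und[e, 1]; v <- und[e, 2]
  rbind(und[-e, , drop = FALSE], c(u, new_node), c(new_node, v), c(new_node, tip))
}

# All NNI neighbours of a raw undirected tree (unique topologies, 2 per
# internal edge).
.nni_neighbors_edges <- function(und, ntip) {
  internal <- which(und[, 1] > ntip & und[, 2] > ntip)
  out <- list()
  for (e in internal) {
    u <- und[e, 1]; v <- und[e, 2]
    nb_u <- .edge_neighbors(und, u, v)
    nb_v <- .edge_neighbors(und, v, u)
    z <- nb_u[1]
    for (x in nb_v) {
      ed <- und
      ed <- .replace_endpoint(ed, v, x, z)
      ed <- .replace_endpoint(ed, u, z, x)
      out[[length(out) + 1L]] <- ed
    }
  }
  out
}

.edge_neighbors <- function(und, node, exclude) {
  nb <- c(und[und[, 1] == node, 2], und[und[, 2] == node, 1])
  nb[nb != exclude]
}

# All SPR neighbours of a raw undirected tree: prune the subtree on the v
# side of each internal-anchored edge {u, v}, dissolve u, and regraft on
# every edge of the remaining component. Supersedes the NNI neighbourhood.
.spr_neighbors_edges <- function(und, ntip) {
  out <- list()
  m <- nrow(und)
  for (e in seq_len(m)) for (dir in 1:2) {
    u <- und[e, dir]; v <- und[e, 3 - dir]
    if (u <= ntip) next               # the anchor node is dissolved, so internal
    nb <- .edge_neighbors(und, u, v)
    if (length(nb) != 2) next
    # nodes of the pruned (v-side) component
    rest <- und[-e, , drop = FALSE]
    in_sub <- .reachable_nodes(rest, v)
    # base tree: drop e, dissolve u into a bridge edge {nb1, nb2}
    keep <- !((rest[, 1] == u & rest[, 2] %in% nb) |
              (rest[, 2] == u & rest[, 1] %in% nb))
    sub_rows <- rest[, 1] %in% in_sub | rest[, 2] %in% in_sub
    base <- rbind(rest[keep & !sub_rows, , drop = FALSE], c(nb[1], nb[2]))
    sub <- rest[sub_rows, , drop = FALSE]
    nb_bridge <- nrow(base)
    for (t in seq_len(nrow(base))) {
      if (t == nb_bridge) next        # regrafting on the bridge restores und
      x <- base[t, 1]; y <- base[t, 2]
      ed <- rbind(base[-t, , drop = FALSE], sub,
                  c(x, u), c(u, y), c(u, v))
      out[[length(out) + 1L]] <- ed
    }
  }
  out
}

.reachable_nodes <- function(und, start) {
  seen <- start
  frontier <- start
  while (length(frontier) > 0) {
    nb <- c(und[und[, 1] %in% frontier, 2], und[und[, 2] %in% frontier, 1])
    nb <- setdiff(unique(nb), seen)
    seen <- c(seen, nb)
    frontier <- nb
  }
  seen
}

# Replace the edge {node, old} with {node, new}.
.replace_endpoint <- function(und, node, old, new) {
  hit <- which((und[, 1] == node & und[, 2] == old) |
               (und[, 2] == node & und[, 1] == old))[1]
  if (und[hit, 1] == node) und[hit, 2] <- new else und[hit, 1] <- new
  und
}

# Canonical topology key over the reference taxa.
.topology_key <- function(und, ntip, taxa) {
  po <- .postorder_from_und(und, ntip)
  sp <- .edges_splits(po, ntip, taxa)
  paste(sort(sp$keys), collapse = "|")
}

.postorder_from_und <- function(und, ntip) {
  root <- und[which(und[, 1] > ntip | und[, 2] > ntip)[1], ]
  root <- root[root > ntip][1]
  .postorder_edges(und, root)
}

# Splits of a raw postorder edge matrix (tips numbered within taxa).
.edges_splits <- function(po, ntip, taxa) {
  ntaxa <- length(taxa)
  nnodes <- max(po)
  below <- matrix(FALSE, nnodes, ntaxa)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(po))) below[po[e, 1], ] <- below[po[e, 1], ] | below[po[e, 2], ]
  keys <- character(0); sides <- list()
  present <- seq_len(ntip)
  for (e in seq_len(nrow(po))) {
    c <- po[e, 2]
    if (c <= ntip) next
    side <- below[c, ]
    sz <- sum(side[seq_len(ntip)])
    if (sz < 2 || sz > ntip - 2) next
    side_n <- .canonical_side(side, present)
    keys <- c(keys, .split_key(side_n, present))
    sides[[length(sides) + 1L]] <- side_n
  }
  list(keys = keys, sides = sides)
}

# ---- search ------------------------------------------------------------------

#' Heuristic parsimony search
#'
#' Random stepwise-addition replicates followed by NNI branch swapping applied
#' to the whole pool of equally short trees until closure (multrees-style),
#' retaining up to `maxtrees` optimal topologies (the cap auto-grows by 100
#' when `auto_increase` is set).
#'
#' @param matrix a [character_matrix()] with >= 4 taxa.
#' @param reps number of random-addition replicates.
#' @param maxtrees initial cap on stored equally short trees.
#' @param auto_increase logical; grow `maxtrees` when the pool fills.
#' @param seed integer seed making the search deterministic.
#' @param weights optional per-included-character weights (bootstrap).
#' @param penalize_side optional logical side vector (over `matrix$taxa`);
#'   trees containing that split incur a large penalty (reverse-constraint
#'   search for Bremer decay).
#' @param swapper branch-swapping neighbourhood: `"spr"` (default) or the
#'   cheaper `"nni"`.
#' @return an object of class `parsimony_result`: `mpts` (multiPhylo),
#'   `length`, `ci`, `log`.
#' @export
heuristic_search <- function(matrix, reps = 10, maxtrees = 100,
                             auto_increase = TRUE, seed = NULL,
                             weights = NULL, penalize_side = NULL,
                             swapper = c("spr", "nni")) {
  swapper <- match.arg(swapper)
  taxa <- matrix$taxa
  n <- length(taxa)
  if (n < 4) stop("heuristic search requires >= 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  PEN <- 1e7
  score <- function(und) {
    po <- .postorder_from_und(und, n)
    s <- .length_edges(po, n, matrix, weights)
    if (!is.null(penalize_side)) {
      sp <- .edges_splits(po, n, taxa)
      key <- .split_key(.canonical_side(penalize_side, seq_len(n)), seq_len(n))
      if (key %in% sp$keys) s <- s + PEN
    }
    s
  }
  best_len <- Inf
  pool <- list(); pool_keys <- character(0)
  log_lines <- character(0)
  maxtrees_now <- maxtrees
  for (rep_i in seq_len(reps)) {
    ord <- sample.int(n)
    und <- cbind(n + 1L, ord[1:3])
    nxt <- n + 2L
    for (t in ord[-(1:3)]) {
      cand <- lapply(seq_len(nrow(und)), function(e)
        .insert_tip_edges(und, e, t, nxt))
      lens <- vapply(cand, score, 0)
      best <- which(lens == min(lens))
      und <- cand[[best[sample.int(length(best), 1)]]]
      nxt <- nxt + 1L
    }
    # pool-closure NNI swapping
    cur_len <- score(und)
    frontier <- list(und)
    keys <- .topology_key(und, n, taxa)
    found <- list(und)
    while (length(frontier) > 0) {
      tr <- frontier[[1]]
      frontier[[1]] <- NULL
      neighbors <- if (swapper == "spr") .spr_neighbors_edges(tr, n)
        else .nni_neighbors_edges(tr, n)
      for (nb in neighbors) {
        l <- score(nb)
        if (l < cur_len) {
          cur_len <- l
          found <- list(nb)
          keys <- .topology_key(nb, n, taxa)
          frontier <- list(nb)
          break
        } else if (l == cur_len) {
          key <- .topology_key(nb, n, taxa)
          if (!(key %in% keys)) {
            if (length(found) >= maxtrees_now) {
              if (auto_increase) {
                maxtrees_now <- maxtrees_now + 100
                log_lines <- c(log_lines,
                               sprintf("maxtrees increased to %d", maxtrees_now))
              } else next
            }
            keys <- c(keys, key)
            found <- c(found, list(nb))
            frontier <- c(frontier, list(nb))
          }
        }
      }
    }
    log_lines <- c(log_lines,
                   sprintf("replicate %d: length %g, %d trees", rep_i, cur_len,
                           length(found)))
    if (cur_len < best_len) {
      best_len <- cur_len
      pool <- found
      pool_keys <- vapply(found, .topology_key, "", ntip = n, taxa = taxa)
    } else if (cur_len == best_len) {
      for (i in seq_along(found)) {
        key <- .topology_key(found[[i]], n, taxa)
        if (!(key %in% pool_keys) && length(pool) < maxtrees_now) {
          pool <- c(pool, list(found[[i]]))
          pool_keys <- c(pool_keys, key)
        }
      }
    }
  }
  .parsimony_result(pool, n, taxa, best_len, matrix, log_lines)
}

#' Exhaustive parsimony search
#'
#' Evaluates every unrooted binary topology (feasible up to ~9 taxa) and
#' returns all most parsimonious trees.
#'
#' @inheritParams heuristic_search
#' @return a `parsimony_result`.
#' @export
exhaustive_search <- function(matrix, weights = NULL, penalize_side = NULL) {
  taxa <- matrix$taxa
  n <- length(taxa)
  if (n < 4 || n > 9) stop("exhaustive search supports 4..9 taxa")
  PEN <- 1e7
  key_pen <- if (!is.null(penalize_side))
    .split_key(.canonical_side(penalize_side, seq_len(n)), seq_len(n))
  topos <- .all_topologies(n)
  best_len <- Inf; pool <- list()
  for (und in topos) {
    po <- .postorder_from_und(und, n)
    s <- .length_edges(po, n, matrix, weights)
    if (!is.null(penalize_side)) {
      sp <- .edges_splits(po, n, taxa)
      if (key_pen %in% sp$keys) s <- s + PEN
    }
    if (s < best_len) {
      best_len <- s
      pool <- list(und)
    } else if (s == best_len) pool <- c(pool, list(und))
  }
  .parsimony_result(pool, n, taxa, best_len,
                    matrix, sprintf("exhaustive: %d topologies", length(topos)))
}

.parsimony_result <- function(pool, ntip, taxa, len, matrix, log_lines) {
  mpts <- lapply(pool, .edges_to_phylo, ntip = ntip, tip_labels = taxa)
  class(mpts) <- "multiPhylo"
  structure(list(mpts = mpts, length = len,
                 ci = consistency_index(matrix, len), log = log_lines),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("parsimony_result: %d MPT(s), length %g, CI %.3f\n",
              length(x$mpts), x$length, x$ci))
  invisible(x)
}

#' Strict consensus of trees
#'
#' Contains exactly the nontrivial splits present in every input tree.
#'
#' @param trees `multiPhylo`/list of trees over the same tips.
#' @param taxa reference taxon ordering (defaults to sorted tips).
#' @return an `ape::phylo` (possibly with polytomies).
#' @export
strict_consensus <- function(trees, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("strict consensus of an empty set")
  if (is.null(taxa)) taxa <- sort(trees[[1]]$tip.label)
  st <- split_table(trees, taxa)
  keep <- st$count == length(trees)
  .tree_from_splits(attr(st, "sides")[keep], taxa)
}

#' Nonparametric bootstrap support
#'
#' Resamples included characters with replacement, searches each pseudoreplicate
#' matrix, and scores every split by the percentage of replicates whose
#' MPT strict consensus contains it.
#'
#' @param matrix a [character_matrix()].
#' @param n_reps number of bootstrap replicates.
#' @param search_reps random-addition replicates per bootstrap search.
#' @param maxtrees cap on trees per search.
#' @param seed integer seed.
#' @return data.frame with `key`, `bs` (percent), plus attribute `sides`.
#' @export
bootstrap_support <- function(matrix, n_reps = 100, search_reps = 2,
                              maxtrees = 50, seed = 1L) {
  set.seed(seed)
  taxa <- matrix$taxa
  inc <- which(matrix$meta$included)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  sides_env <- new.env(hash = TRUE, parent = emptyenv())
  for (b in seq_len(n_reps)) {
    draw <- sample(seq_along(inc), replace = TRUE)
    w <- tabulate(draw, nbins = length(inc))
    res <- heuristic_search(matrix, reps = search_reps, maxtrees = maxtrees,
                            seed = sample.int(2^30, 1), weights = w)
    cons_splits <- .consensus_split_keys(res$mpts, taxa)
    for (i in seq_along(cons_splits$keys)) {
      k <- cons_splits$keys[i]
      assign(k, get0(k, envir = counts, ifnotfound = 0) + 1, envir = counts)
      if (is.null(get0(k, envir = sides_env)))
        assign(k, cons_splits$sides[[i]], envir = sides_env)
    }
  }
  keys <- ls(counts)
  df <- data.frame(key = keys,
                   bs = vapply(keys, function(k) 100 * get(k, envir = counts) / n_reps, 0),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$bs, df$key), ]
  rownames(df) <- NULL
  attr(df, "sides") <- lapply(df$key, function(k) get(k, envir = sides_env))
  attr(df, "taxa") <- taxa
  df
}

.consensus_split_keys <- function(trees, taxa) {
  st <- split_table(trees, taxa)
  keep <- st$count == length(trees)
  list(keys = st$key[keep], sides = attr(st, "sides")[keep])
}

#' Bremer (decay) index of a clade
#'
#' Extra steps needed by the shortest tree in which the given taxon set is
#' *not* monophyletic, relative to the most-parsimonious length — computed by
#' exhaustive enumeration for small taxon sets and reverse-constraint
#' (penalized) heuristic search otherwise.
#'
#' @param matrix a [character_matrix()].
#' @param taxon_set character vector of taxa forming the clade of interest.
#' @param result a `parsimony_result` for `matrix` (computed if `NULL`).
#' @param reps,maxtrees,seed search settings for the reverse-constraint search.
#' @return integer decay index `D >= 0`.
#' @export
bremer_decay <- function(matrix, taxon_set, result = NULL, reps = 10,
                         maxtrees = 100, seed = 1L) {
  taxa <- matrix$taxa
  n <- length(taxa)
  if (is.null(result)) {
    result <- if (n <= 9) exhaustive_search(matrix)
      else heuristic_search(matrix, reps = reps, maxtrees = maxtrees, seed = seed)
  }
  side <- taxa %in% taxon_set
  key <- .split_key(.canonical_side(side, seq_len(n)), seq_len(n))
  cons <- .consensus_split_keys(result$mpts, taxa)
  if (!(key %in% cons$keys))
    stop("taxon set is not a clade in the strict consensus of the MPTs")
  anti <- if (n <= 9) exhaustive_search(matrix, penalize_side = side)
    else heuristic_search(matrix, reps = reps, maxtrees = maxtrees,
                          seed = seed, penalize_side = side)
  as.integer(round(anti$length - result$length))
}
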