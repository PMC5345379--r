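# Shared fixtures and independent oracles for the suite. Oracles deliberately
# avoid the package's pruning/search code paths: likelihoods are recomputed by
# explicit enumeration over internal-state assignments, parsimony scores by
# phangorn and by enumeration.

# A reproducible random matrix fixture (singletons, missing, polymorphism).
fixture_matrix <- function(n_taxa = 10, n_chars = 20, seed = 1,
                           missing_rate = 0.1, polymorphism_rate = 0.05,
                           alpha_true = NA, depth = 1) {
  cfg <- sim_config(n_taxa = n_taxa, n_chars = n_chars, seed = seed,
                    missing_rate = missing_rate,
                    polymorphism_rate = polymorphism_rate,
                    alpha_true = alpha_true, depth = depth)
  tr <- simulate_tree(cfg)
  list(tree = tr, matrix = simulate_matrix(tr, cfg), config = cfg)
}

# Enumeration oracle: likelihood of one column by brute force over all
# internal-state assignments, mixing over gamma categories, with optional
# conditioning on variability. Completely independent of the pruning code.
brute_column_loglik <- function(tree, masks, k, ordered = FALSE,
                                rates = 1, conditioning = "all") {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  Q <- rate_matrix(k, ordered)
  lik_for_masks <- function(m) {
    tot <- 0
    for (r in rates) {
      Ps <- lapply(tree$edge.length, function(nu) transition_probs(Q, nu, r))
      internal_ids <- ntip + seq_len(nnode)
      grid <- do.call(expand.grid, rep(list(seq_len(k) - 1L), nnode))
      s <- 0
      root <- tree$edge[nrow(tree$edge), 1]
      for (g in seq_len(nrow(grid))) {
        assign_int <- as.integer(grid[g, ])
        state_of <- function(node) assign_int[node - ntip]
        p <- 1 / k  # uniform root prior
        for (e in seq_len(nrow(tree$edge))) {
          a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
          sa <- state_of(a)
          if (b <= ntip) {
            allowed <- which(bitwAnd(m[b], bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
            p <- p * sum(Ps[[e]][sa + 1L, allowed])
          } else {
            p <- p * Ps[[e]][sa + 1L, state_of(b) + 1L]
          }
        }
        # root must match its assigned state (root is internal)
        s <- s + p * (1)
      }
      tot <- tot + s / length(rates)
    }
    tot
  }
  L <- lik_for_masks(masks)
  if (conditioning == "variable") {
    cmass <- 0
    for (st in seq_len(k) - 1L) {
      const_masks <- rep(bitwShiftL(1L, st), ntip)
      cmass <- cmass + lik_for_masks(const_masks)
    }
    return(log(L) - log(1 - cmass))
  }
  log(L)
}

# Convert a morphoclade matrix to a phangorn phyDat (singleton and ambiguous
# cells via a contrast matrix), for cross-checking parsimony scores.
as_phyDat <- function(m, char_idx = NULL) {
  if (is.null(char_idx)) char_idx <- which(m$meta$included)
  kmax <- max(m$meta$k[char_idx])
  masks_seen <- sort(unique(as.vector(m$cells[, char_idx, drop = FALSE])))
  contrast <- t(vapply(masks_seen, function(msk)
    as.numeric(bitwAnd(msk, bitwShiftL(1L, seq_len(kmax) - 1L)) != 0L),
    numeric(kmax)))
  dimnames(contrast) <- list(as.character(masks_seen), as.character(seq_len(kmax) - 1L))
  dat <- matrix(as.character(m$cells[, char_idx, drop = FALSE]),
                nrow = length(m$taxa), dimnames = list(m$taxa, NULL))
  phangorn::phyDat(dat, type = "USER", contrast = contrast)
}

# Small deterministic 4-taxon tree.
tree4 <- function() ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.05);")

expect_close <- function(a, b, tol = 1e-9) expect_lt(max(abs(a - b)), tol)

.full_mask_for_test <- function(k) bitwShiftL(1L, as.integer(k)) - 1L
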