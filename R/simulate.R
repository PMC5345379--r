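# Seeded synthetic data: pure-birth trees, Mk(+gamma)-evolved discrete
# matrices conditioned on variability, Brownian quantitative trait tables,
# raw multi-observation inputs for majority-coding, and a metadata fixture
# shaped like a real morphological character list (163 characters, 27
# quantitative, stated ordered and excluded sets).

#' Simulation configuration
#'
#' @param n_taxa number of tips (>= 4 for tree-based outputs).
#' @param n_chars number of discrete characters.
#' @param k_probs named numeric vector: probability of each state count, e.g.
#'   `c("2" = 0.75, "3" = 0.2, "4" = 0.05)` (morphological matrices are
#'   dominated by binary characters).
#' @param p_ordered probability that a character with k >= 3 is ordered.
#' @param alpha_true gamma shape of across-character rate variation
#'   (`NA` for equal rates).
#' @param depth tree depth in expected changes per character.
#' @param variable_only condition each character on being variable
#'   (resampling until non-constant), matching the ascertainment built into
#'   morphological matrices.
#' @param missing_rate per-cell probability of replacement by the full
#'   state-set.
#' @param polymorphism_rate per-cell probability of widening a singleton to a
#'   two-state set.
#' @param n_quant number of quantitative trait columns.
#' @param drift_sd Brownian standard deviation per unit branch length for
#'   quantitative traits.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20, n_chars = 100,
                       k_probs = c("2" = 0.75, "3" = 0.20, "4" = 0.05),
                       p_ordered = 0.1, alpha_true = 0.5, depth = 0.8,
                       variable_only = TRUE, missing_rate = 0,
                       polymorphism_rate = 0, n_quant = 0, drift_sd = 1,
                       seed = 1L) {
  stopifnot(n_taxa >= 2, n_chars >= 0, all(k_probs >= 0), sum(k_probs) > 0,
            p_ordered >= 0, p_ordered <= 1,
            missing_rate >= 0, missing_rate <= 1,
            polymorphism_rate >= 0, polymorphism_rate <= 1,
            depth > 0, drift_sd >= 0)
  structure(list(n_taxa = n_taxa, n_chars = n_chars,
                 k_probs = k_probs / sum(k_probs), p_ordered = p_ordered,
                 alpha_true = alpha_true, depth = depth,
                 variable_only = variable_only, missing_rate = missing_rate,
                 polymorphism_rate = polymorphism_rate, n_quant = n_quant,
                 drift_sd = drift_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth tree
#'
#' Yule topology with branch lengths rescaled so the root-to-tip depth equals
#' `config$depth` (expected changes per character). Deterministic given the
#' seed.
#'
#' @param config a [sim_config()].
#' @return a rooted `ape::phylo` with tips `t1..tN`.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  n <- config$n_taxa
  if (n == 2) {
    tr <- ape::read.tree(text = "(t1:1,t2:1);")
    tr$edge.length <- tr$edge.length * config$depth / 2
    return(tr)
  }
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n))
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$depth / d
  tr
}

#' Simulate a discrete character matrix along a tree
#'
#' Each character draws a state count and ordered flag, a relative rate from
#' Gamma(`alpha_true`, `alpha_true`) (mean 1), a uniform root state, and then
#' evolves by the same Mk rate matrices the likelihood engine uses. With
#' `variable_only` a character is resampled until non-constant, reproducing
#' the ascertainment the Mkv correction models. Missing cells and two-state
#' polymorphism sets are injected afterwards at the configured rates.
#'
#' @param tree a `phylo` with branch lengths in expected changes.
#' @param config a [sim_config()]; the seed is advanced independently of
#'   [simulate_tree()] so tree and matrix can share a config.
#' @return a [character_matrix()] whose metadata records each character's
#'   simulated `k` and ordered flag.
#' @export
simulate_matrix <- function(tree, config) {
  set.seed(config$seed + 1L)
  taxa <- tree$tip.label
  n <- length(taxa)
  tree <- stats::reorder(tree, "postorder")
  nchar_ <- config$n_chars
  ks <- as.integer(sample(names(config$k_probs), nchar_, replace = TRUE,
                          prob = config$k_probs))
  ordered <- ks >= 3 & stats::runif(nchar_) < config$p_ordered
  draw_rate <- function() {
    if (is.na(config$alpha_true)) 1
    else stats::rgamma(1, shape = config$alpha_true, rate = config$alpha_true)
  }
  cells <- matrix(0L, n, nchar_)
  Ps <- new.env(parent = emptyenv())  # cache eigen per (k, ordered)
  for (j in seq_len(nchar_)) {
    key <- paste(ks[j], ordered[j])
    e <- get0(key, envir = Ps)
    if (is.null(e)) {
      e <- eigen(rate_matrix(ks[j], ordered[j]), symmetric = TRUE)
      assign(key, e, envir = Ps)
    }
    # the whole character (its rate included) is resampled until variable,
    # so conditioning matches the Mkv ascertainment model
    repeat {
      states <- .evolve_column(tree, ks[j], e, draw_rate())
      if (!config$variable_only || length(unique(states)) > 1) break
    }
    cells[, j] <- bitwShiftL(1L, states)
  }
  # inject missingness and polymorphism
  for (j in seq_len(nchar_)) {
    full <- .full_mask(ks[j])
    miss <- stats::runif(n) < config$missing_rate
    cells[miss, j] <- full
    if (config$polymorphism_rate > 0 && ks[j] >= 2) {
      poly <- !miss & stats::runif(n) < config$polymorphism_rate
      for (i in which(poly)) {
        s <- .states_from_mask(cells[i, j])
        other <- sample(setdiff(seq_len(ks[j]) - 1L, s), 1)
        cells[i, j] <- bitwOr(cells[i, j], bitwShiftL(1L, other))
      }
    }
  }
  meta <- character_meta(ks, ordered = ordered)
  character_matrix(cells, taxa, meta)
}

# Evolve one character down a postorder tree; returns tip states (0-based).
.evolve_column <- function(tree, k, e, rate) {
  ntip <- length(tree$tip.label)
  nnodes <- ntip + tree$Nnode
  edge <- tree$edge
  root <- edge[nrow(edge), 1]
  state <- integer(nnodes)
  state[root] <- sample.int(k, 1) - 1L
  for (r in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[r, 1]; c <- edge[r, 2]
    t <- tree$edge.length[r] * rate
    P <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
    pr <- P[state[p] + 1L, ]
    pr[pr < 0] <- 0
    state[c] <- sample.int(k, 1, prob = pr) - 1L
  }
  state[seq_len(ntip)]
}

#' Simulate quantitative traits by Brownian drift
#'
#' Independent Brownian motion along the tree per character, variance
#' `drift_sd^2` per unit branch length (via `ape::rTraitCont`).
#'
#' @param tree a `phylo` with branch lengths.
#' @param config a [sim_config()] (`n_quant`, `drift_sd`, `seed`).
#' @return a data.frame: `taxon` column plus one numeric column per trait.
#' @export
simulate_quantitative <- function(tree, config) {
  set.seed(config$seed + 2L)
  n <- config$n_quant
  out <- data.frame(taxon = tree$tip.label, stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    out[[paste0("q", j)]] <-
      as.numeric(ape::rTraitCont(tree, model = "BM", sigma = config$drift_sd))
  }
  out
}

#' Raw multi-observation qualitative inputs
#'
#' Emulates the pre-coding situation in which several specimens per species
#' were scored and some characters are intraspecifically polymorphic: for
#' each taxon and character, draws `n_obs` observations around the taxon's
#' true state.
#'
#' @param matrix a [character_matrix()] of true (singleton) states.
#' @param n_obs observations per taxon and character.
#' @param flip_rate probability that one observation deviates to a
#'   neighbouring state.
#' @param seed integer seed.
#' @return a list (one element per character) of named lists mapping taxon to
#'   an integer observation vector, as consumed by [code_matrix()].
#' @export
simulate_observations <- function(matrix, n_obs = 3, flip_rate = 0.2,
                                  seed = 1L) {
  set.seed(seed)
  lapply(seq_len(ncol(matrix$cells)), function(j) {
    k <- matrix$meta$k[j]
    obs <- lapply(seq_along(matrix$taxa), function(i) {
      s <- .states_from_mask(matrix$cells[i, j])[1]
      o <- rep(s, n_obs)
      flips <- stats::runif(n_obs) < flip_rate
      if (any(flips) && k >= 2)
        o[flips] <- vapply(o[flips], function(x)
          sample(setdiff(seq_len(k) - 1L, x), 1), 0L)
      o
    })
    names(obs) <- matrix$taxa
    obs
  })
}

#' Character-list metadata fixture
#'
#' Per-character metadata shaped like the character list of a large adult-
#' morphology matrix: 163 characters of which 27 are quantitative (binary
#' after median coding), 13 ordered multistate (characters 6, 9, 22, 27, 29,
#' 37, 44, 60, 85, 123, 133, 145 and 161), and 4 excluded (9, 34, 46 and 162,
#' the fossoriality-linked and habitat characters), leaving 159 included.
#' State counts per character follow the printed state lists.
#'
#' @return a [character_meta()] data.frame with 163 rows.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_meta.tsv", package = "morphoclade")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta <- character_meta(df$k, kind = df$kind, ordered = df$ordered == 1,
                         included = df$included == 1)
  stopifnot(nrow(meta) == 163)
  meta
}
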