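# Mk / Mkv likelihood engine for k-state morphological characters: symmetric
# (Jukes-Cantor-like) rate matrices, ordered-state chains, discrete-gamma rate
# variation, ambiguity/missing handling, and the variable-characters-only
# ascertainment correction (the "v" of Mkv): each character's likelihood is
# divided by the probability of being variable on the tree.

#' Specify an Mk/Mkv model
#'
#' @param gamma logical; gamma-distributed rate variation across characters.
#' @param ncat number of discrete gamma categories (default 4).
#' @param alpha gamma shape (> 0); ignored when `gamma = FALSE`.
#' @param conditioning `"variable"` (Mkv: condition each character on being
#'   variable, the correction for matrices that omit constant characters) or
#'   `"all"` (plain Mk).
#' @param gamma_method `"mean"` (category means, default) or `"median"`
#'   (category medians, renormalized to mean 1).
#' @return an object of class `mk_model_spec`.
#' @export
mk_model_spec <- function(gamma = FALSE, ncat = 4L, alpha = 1,
                          conditioning = c("variable", "all"),
                          gamma_method = c("mean", "median")) {
  conditioning <- match.arg(conditioning)
  gamma_method <- match.arg(gamma_method)
  stopifnot(ncat >= 1, alpha > 0)
  structure(list(gamma = gamma, ncat = as.integer(ncat), alpha = alpha,
                 conditioning = conditioning, gamma_method = gamma_method),
            class = "mk_model_spec")
}

#' Discrete-gamma category rates
#'
#' Equal-probability discretization of the Gamma(shape, rate = shape)
#' distribution (mean 1): category representatives are the conditional means
#' (default) or the renormalized category medians.
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories.
#' @param method `"mean"` or `"median"`.
#' @return numeric vector of `ncat` rates with mean exactly 1.
#' @export
gamma_category_rates <- function(alpha, ncat, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, ncat >= 1)
  if (ncat == 1) return(1)
  if (method == "mean") {
    b <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
    # E[X 1(X <= b)] for X ~ Gamma(a, a) equals F_{Gamma(a+1, a)}(b)
    f <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
    r <- ncat * diff(f)
  } else {
    q <- stats::qgamma((2 * seq_len(ncat) - 1) / (2 * ncat),
                       shape = alpha, rate = alpha)
    r <- q / mean(q)
  }
  r
}

#' Mk rate matrix
#'
#' Symmetric k-state rate matrix: all changes equally likely (unordered) or
#' restricted to adjacent states (ordered chain). Scaled so the expected rate
#' under the uniform stationary distribution is one change per unit branch
#' length.
#'
#' @param k number of states (>= 2).
#' @param ordered logical; adjacent-transition chain when `TRUE`.
#' @return a `k x k` rate matrix with zero row sums.
#' @export
rate_matrix <- function(k, ordered = FALSE) {
  k <- as.integer(k)
  if (k < 2) stop("rate_matrix requires k >= 2")
  if (!ordered) {
    a <- 1 / (k - 1)
    Q <- matrix(a, k, k)
  } else {
    a <- k / (2 * (k - 1))
    Q <- matrix(0, k, k)
    for (i in seq_len(k - 1)) {
      Q[i, i + 1] <- a
      Q[i + 1, i] <- a
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities along a branch
#'
#' `P = exp(Q * nu * r)` by symmetric eigendecomposition.
#'
#' @param Q rate matrix from [rate_matrix()] (symmetric).
#' @param nu branch length (>= 0) in expected changes per character.
#' @param r rate multiplier (> 0).
#' @return row-stochastic `k x k` probability matrix.
#' @export
transition_probs <- function(Q, nu, r = 1) {
  if (nu < 0) stop("negative branch length")
  stopifnot(r > 0)
  e <- eigen(Q, symmetric = TRUE)
  P <- e$vectors %*% diag(exp(e$values * nu * r), nrow(Q)) %*% t(e$vectors)
  P[P < 0] <- 0
  P
}

# ---- pruning machinery -------------------------------------------------------

# Group included characters by (k, ordered); precompute eigen pieces and leaf
# partials (with k constant dummy columns appended per group for the
# ascertainment term). Tip partial order follows `tip_labels`.
.mk_precompute <- function(matrix, spec, tip_labels) {
  validate_char_matrix(matrix)
  row_of <- match(tip_labels, matrix$taxa)
  if (anyNA(row_of)) stop("tree tips do not match matrix taxa")
  inc <- which(matrix$meta$included)
  ntip <- length(tip_labels)
  groups <- list()
  if (length(inc) > 0) {
    key <- paste(matrix$meta$k[inc], matrix$meta$ordered[inc])
    for (kk in unique(key)) {
      idx <- inc[key == kk]
      k <- matrix$meta$k[idx[1]]
      ordered <- matrix$meta$ordered[idx[1]]
      if (k < 2)
        stop(sprintf("character %d: k = %d has no likelihood model (k >= 2 required)",
                     idx[1], k))
      e <- eigen(rate_matrix(k, ordered), symmetric = TRUE)
      ncol_g <- length(idx)
      tip_part <- array(0, dim = c(k, ncol_g + k, ntip))
      for (i in seq_len(ntip)) {
        masks <- matrix$cells[row_of[i], idx]
        for (j in seq_len(ncol_g)) {
          st <- .states_from_mask(masks[j])
          tip_part[st + 1L, j, i] <- 1
        }
        for (s in seq_len(k)) tip_part[s, ncol_g + s, i] <- 1
      }
      groups[[length(groups) + 1L]] <- list(
        idx = idx, k = k, ordered = ordered,
        U = e$vectors, lambda = e$values, tip_part = tip_part)
    }
  }
  list(groups = groups, ntip = ntip, tip_labels = tip_labels)
}

# Fast total corrected log-likelihood (hot path of the MCMC).
.mk_loglik_total <- function(tree, pre, spec) {
  tree <- stats::reorder(tree, "postorder")
  nnodes_total <- pre$ntip + tree$Nnode
  rates <- if (isTRUE(spec$gamma))
    gamma_category_rates(spec$alpha, spec$ncat, spec$gamma_method) else 1
  total <- 0
  for (g in pre$groups) {
    ncol_g <- length(g$idx)
    lmat <- .mk_prune_group_cpp(tree$edge, tree$edge.length, pre$ntip,
                                nnodes_total, g$tip_part, g$k, ncol_g + g$k,
                                g$U, g$lambda, rates)
    lcol <- .col_logmeanexp(lmat)
    if (spec$conditioning == "variable") {
      c_g <- sum(exp(lcol[ncol_g + seq_len(g$k)]))
      if (c_g >= 1)
        stop("constant-pattern probability is 1 (no positive branch length): cannot condition on variability")
      total <- total + sum(lcol[seq_len(ncol_g)]) - ncol_g * log1p(-c_g)
    } else total <- total + sum(lcol[seq_len(ncol_g)])
  }
  total
}

# Per-character corrected log-likelihoods given a (postorder) tree.
# Returns list(per_char = data.frame, total).
.mk_loglik <- function(tree, pre, spec) {
  tree <- stats::reorder(tree, "postorder")
  nnodes_total <- pre$ntip + tree$Nnode
  rates <- if (isTRUE(spec$gamma))
    gamma_category_rates(spec$alpha, spec$ncat, spec$gamma_method) else 1
  idx_all <- integer(0); lnL <- numeric(0); cmass <- numeric(0)
  for (g in pre$groups) {
    ncol_g <- length(g$idx)
    lmat <- .mk_prune_group_cpp(tree$edge, tree$edge.length, pre$ntip,
                                nnodes_total, g$tip_part, g$k, ncol_g + g$k,
                                g$U, g$lambda, rates)
    lcol <- .col_logmeanexp(lmat)
    c_g <- sum(exp(lcol[ncol_g + seq_len(g$k)]))
    idx_all <- c(idx_all, g$idx)
    lnL <- c(lnL, lcol[seq_len(ncol_g)])
    cmass <- c(cmass, rep(c_g, ncol_g))
  }
  o <- order(idx_all)
  idx_all <- idx_all[o]; lnL <- lnL[o]; cmass <- cmass[o]
  if (spec$conditioning == "variable") {
    if (any(cmass >= 1))
      stop("constant-pattern probability is 1 (no positive branch length): cannot condition on variability")
    corrected <- lnL - log1p(-cmass)
  } else corrected <- lnL
  list(per_char = data.frame(index = idx_all, lnL = lnL,
                             const_mass = cmass, corrected = corrected),
       total = sum(corrected))
}

.logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Column-wise logmeanexp of a small (ncat x ncol) matrix, loop-free over
# columns (called once per MCMC cycle).
.col_logmeanexp <- function(lmat) {
  ncat <- nrow(lmat)
  if (ncat == 1) return(as.numeric(lmat[1, ]))
  mx <- lmat[1, ]
  for (r in 2:ncat) mx <- pmax(mx, lmat[r, ])
  mx + log(colMeans(exp(lmat - rep(mx, each = ncat))))
}

#' Log-likelihood of a single character column
#'
#' Computes the pruning likelihood of one character on a tree, together with
#' the constant-pattern mass `c` (the probability that all taxa share one
#' state) and the ascertainment-corrected value `lnL - log(1 - c)` used under
#' variable-characters-only conditioning.
#'
#' @param tree an `ape::phylo` with branch lengths; tips must match the
#'   column's taxa.
#' @param column integer state-set bitmask vector named by taxon, or a
#'   single-character [character_matrix()].
#' @param meta single-row [character_meta()] for the character (used when
#'   `column` is a bare vector).
#' @param spec an [mk_model_spec()].
#' @return list with `lnL`, `const_mass`, `corrected`.
#' @export
character_loglik <- function(tree, column, meta = NULL, spec = mk_model_spec()) {
  if (inherits(column, "char_matrix")) {
    m <- column
  } else {
    cells <- matrix(as.integer(column), ncol = 1)
    m <- character_matrix(cells, names(column), meta)
  }
  if (sum(m$meta$included) != 1) stop("character_loglik expects one included character")
  if (spec$conditioning == "variable") .check_not_all_missing(m)
  pre <- .mk_precompute(m, spec, tree$tip.label)
  res <- .mk_loglik(tree, pre, spec)
  list(lnL = res$per_char$lnL[1], const_mass = res$per_char$const_mass[1],
       corrected = res$per_char$corrected[1])
}

#' Total log-likelihood of a character matrix
#'
#' Sum of per-character (corrected) log-likelihoods over included characters;
#' excluded characters contribute exactly zero.
#'
#' @param tree an `ape::phylo` with branch lengths over the matrix taxa.
#' @param matrix a [character_matrix()].
#' @param spec an [mk_model_spec()].
#' @param per_character return the per-character breakdown as well.
#' @return total log-likelihood, or (with `per_character = TRUE`) a list
#'   `total`, `per_char`.
#' @export
matrix_loglik <- function(tree, matrix, spec = mk_model_spec(),
                          per_character = FALSE) {
  if (sum(matrix$meta$included) == 0)
    return(if (per_character)
      list(total = 0, per_char = data.frame(index = integer(0), lnL = numeric(0),
                                            const_mass = numeric(0),
                                            corrected = numeric(0)))
      else 0)
  if (spec$conditioning == "variable") .check_not_all_missing(matrix)
  pre <- .mk_precompute(matrix, spec, tree$tip.label)
  res <- .mk_loglik(tree, pre, spec)
  if (per_character) res else res$total
}

.check_not_all_missing <- function(matrix) {
  for (j in which(matrix$meta$included)) {
    full <- .full_mask(matrix$meta$k[j])
    if (all(matrix$cells[, j] == full))
      stop(sprintf("character %d is entirely missing: conditioning on variability is undefined", j))
  }
}

#' Per-character likelihood report
#'
#' Writes a tab-separated report of per-character log-likelihoods and
#' ascertainment terms.
#'
#' @param tree,matrix,spec as in [matrix_loglik()].
#' @param path output TSV path.
#' @return the report data.frame, invisibly.
#' @export
write_likelihood_report <- function(tree, matrix, spec, path) {
  res <- matrix_loglik(tree, matrix, spec, per_character = TRUE)
  rep_df <- data.frame(
    index = res$per_char$index,
    k = matrix$meta$k[res$per_char$index],
    ordered = matrix$meta$ordered[res$per_char$index],
    lnL = res$per_char$lnL,
    correction = -log1p(-res$per_char$const_mass)
  )
  utils::write.table(rep_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep_df)
}
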