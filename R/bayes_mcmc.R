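# Bayesian MCMC over (topology, branch lengths, gamma shape) under Mk/Mkv.
# Single cold chain per run; several independent runs with cross-run ASDSF as
# the convergence diagnostic. Proposals: uniform NNI (symmetric: the NNI
# neighbourhood of an unrooted binary tree has constant size 2(n-3)),
# log-scale multipliers on a random branch length and on the gamma shape
# (with the standard Hastings correction).

#' MCMC configuration
#'
#' @param cycles chain length (one proposal per cycle).
#' @param sample_every sampling interval; draws are taken at the start of
#'   every `sample_every`-cycle block (see [expected_draws()]).
#' @param n_runs number of independent runs for [run_analysis()].
#' @param burnin_fraction proportion of draws discarded as burn-in.
#' @param seed base integer seed; run `i` uses `seeds[i]`.
#' @param seeds optional explicit per-run seeds (default `seed + 0:(n_runs-1)`).
#' @param weights named proposal weights `nni`, `blen`, `alpha`
#'   (non-negative, not all zero; `alpha` is ignored without gamma).
#' @param blen_prior_mean mean of the i.i.d. exponential branch-length prior
#'   (expected changes per character).
#' @param alpha_prior_mean mean of the exponential prior on the gamma shape.
#' @param asdsf_threshold target average standard deviation of split
#'   frequencies declaring topological convergence.
#' @param asdsf_min_freq splits below this frequency in every run are ignored
#'   by the ASDSF.
#' @param sample_prior if `TRUE` the likelihood is held constant (prior-only
#'   sampling, for validating the proposal machinery).
#' @param tune_blen,tune_alpha multiplier window widths (log scale).
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(cycles = 100000, sample_every = 100, n_runs = 4,
                        burnin_fraction = 0.25, seed = 1L, seeds = NULL,
                        weights = c(nni = 0.5, blen = 0.4, alpha = 0.1),
                        blen_prior_mean = 0.1, alpha_prior_mean = 1,
                        asdsf_threshold = 0.01, asdsf_min_freq = 0.10,
                        sample_prior = FALSE,
                        tune_blen = 2 * log(2), tune_alpha = 2 * log(1.5)) {
  stopifnot(cycles >= 0, sample_every >= 1, cycles == 0 || cycles >= sample_every,
            n_runs >= 1, burnin_fraction >= 0, burnin_fraction < 1,
            all(weights >= 0), sum(weights) > 0,
            blen_prior_mean > 0, alpha_prior_mean > 0)
  if (is.null(seeds)) seeds <- as.integer(seed) + seq_len(n_runs) - 1L
  structure(list(cycles = cycles, sample_every = sample_every, n_runs = n_runs,
                 burnin_fraction = burnin_fraction, seed = as.integer(seed),
                 seeds = as.integer(seeds), weights = weights,
                 blen_prior_mean = blen_prior_mean,
                 alpha_prior_mean = alpha_prior_mean,
                 asdsf_threshold = asdsf_threshold,
                 asdsf_min_freq = asdsf_min_freq,
                 sample_prior = sample_prior,
                 tune_blen = tune_blen, tune_alpha = tune_alpha),
            class = "mcmc_config")
}

# Uniform random unrooted binary topology (random sequential addition on a
# uniformly chosen edge yields the uniform distribution over topologies).
.random_topology <- function(taxa) {
  n <- length(taxa)
  und <- cbind(n + 1L, sample.int(n, 3))
  nxt <- n + 2L
  remaining <- setdiff(sample.int(n), und[, 2])
  for (t in remaining) {
    e <- sample.int(nrow(und), 1)
    und <- .insert_tip_edges(und, e, t, nxt)
    nxt <- nxt + 1L
  }
  .edges_to_phylo(und, n, taxa)
}

# One uniform NNI move on a postorder phylo with basal trichotomy.
# Returns the new tree (postorder) or NULL if no internal edge exists.
.propose_nni <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  internal <- which(edge[, 2] > ntip)
  if (length(internal) == 0) return(NULL)
  e <- internal[sample.int(length(internal), 1)]
  p <- edge[e, 1]; c <- edge[e, 2]
  child_rows <- which(edge[, 1] == c)
  s_rows <- which(edge[, 1] == p & edge[, 2] != c)
  x_row <- child_rows[sample.int(2, 1)]
  s_row <- s_rows[1]
  edge[s_row, 1] <- c
  edge[x_row, 1] <- p
  tree$edge <- edge
  attr(tree, "order") <- NULL
  stats::reorder(tree, "postorder")
}

#' Run one MCMC chain
#'
#' Metropolis–Hastings sampling of topology, branch lengths and (with gamma)
#' the shape parameter, starting from a uniformly random topology with
#' prior-drawn branch lengths. Deterministic given the seed.
#'
#' @param matrix a [character_matrix()] with >= 4 taxa.
#' @param spec an [mk_model_spec()].
#' @param config an [mcmc_config()].
#' @param run_id which run (selects the per-run seed).
#' @return a [tree_sample()] with acceptance rates in attribute `acceptance`.
#' @export
run_chain <- function(matrix, spec, config, run_id = 1L) {
  taxa <- matrix$taxa
  n <- length(taxa)
  if (n < 4) stop("MCMC requires >= 4 taxa (no topology to sample)")
  set.seed(config$seeds[run_id])

  w <- config$weights
  if (!isTRUE(spec$gamma)) w["alpha"] <- 0
  w <- w / sum(w)

  tree <- .random_topology(taxa)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / config$blen_prior_mean)
  alpha <- if (isTRUE(spec$gamma)) stats::rexp(1, 1 / config$alpha_prior_mean) else NA_real_

  pre <- .mk_precompute(matrix, spec, tree$tip.label)
  if (spec$conditioning == "variable") .check_not_all_missing(matrix)
  loglik <- function(tr, a) {
    if (config$sample_prior) return(0)
    sp <- spec
    if (isTRUE(spec$gamma)) sp$alpha <- a
    .mk_loglik_total(tr, pre, sp)
  }
  logprior_blen <- function(tr)
    sum(stats::dexp(tr$edge.length, rate = 1 / config$blen_prior_mean, log = TRUE))
  logprior_alpha <- function(a)
    if (isTRUE(spec$gamma)) stats::dexp(a, rate = 1 / config$alpha_prior_mean, log = TRUE) else 0

  cur_ll <- loglik(tree, alpha)
  cur_lp <- logprior_blen(tree) + logprior_alpha(alpha)

  ndraws <- expected_draws(config$cycles, config$sample_every)
  trees <- vector("list", ndraws)
  lnLs <- numeric(ndraws); alphas <- numeric(ndraws); cyc_rec <- integer(ndraws)
  next_rec <- 1L
  acc <- c(nni = 0, blen = 0, alpha = 0)
  tot <- c(nni = 0, blen = 0, alpha = 0)

  record <- function(cyc) {
    trees[[next_rec]] <<- tree
    lnLs[next_rec] <<- cur_ll
    alphas[next_rec] <<- alpha
    cyc_rec[next_rec] <<- cyc
    next_rec <<- next_rec + 1L
  }

  cyc <- 0L
  while (cyc < config$cycles || (config$cycles == 0 && cyc == 0L)) {
    if (next_rec <= ndraws && cyc == (next_rec - 1L) * config$sample_every)
      record(cyc)
    if (config$cycles == 0) break
    move <- sample(names(w), 1, prob = w)
    tot[move] <- tot[move] + 1
    if (move == "nni") {
      prop <- .propose_nni(tree)
      new_ll <- loglik(prop, alpha)
      lr <- new_ll - cur_ll  # lengths permuted, prior unchanged; symmetric
      if (log(stats::runif(1)) < lr) {
        tree <- prop; cur_ll <- new_ll
        acc[move] <- acc[move] + 1
      }
    } else if (move == "blen") {
      e <- sample.int(nrow(tree$edge), 1)
      m <- exp(config$tune_blen * (stats::runif(1) - 0.5))
      prop <- tree
      prop$edge.length[e] <- tree$edge.length[e] * m
      new_ll <- loglik(prop, alpha)
      new_lp <- logprior_blen(prop) + logprior_alpha(alpha)
      lr <- (new_ll + new_lp) - (cur_ll + cur_lp) + log(m)
      if (log(stats::runif(1)) < lr) {
        tree <- prop; cur_ll <- new_ll; cur_lp <- new_lp
        acc[move] <- acc[move] + 1
      }
    } else {
      m <- exp(config$tune_alpha * (stats::runif(1) - 0.5))
      a2 <- alpha * m
      new_ll <- loglik(tree, a2)
      new_lp <- logprior_blen(tree) + logprior_alpha(a2)
      lr <- (new_ll + new_lp) - (cur_ll + cur_lp) + log(m)
      if (log(stats::runif(1)) < lr) {
        alpha <- a2; cur_ll <- new_ll; cur_lp <- new_lp
        acc[move] <- acc[move] + 1
      }
    }
    cyc <- cyc + 1L
  }
  if (config$cycles == 0 && next_rec == 1L) record(0L)

  out <- tree_sample(trees[seq_len(next_rec - 1L)], lnLs[seq_len(next_rec - 1L)],
                     alphas[seq_len(next_rec - 1L)], cyc_rec[seq_len(next_rec - 1L)],
                     run_id)
  attr(out, "acceptance") <- ifelse(tot > 0, acc / tot, NA)
  out
}

#' Average standard deviation of split frequencies
#'
#' For every nontrivial bipartition reaching `min_freq` in at least one run,
#' the standard deviation of its frequency across runs; the ASDSF is the mean
#' over those splits (0 when none qualify). Small values indicate the runs
#' sample the same posterior over topologies.
#'
#' @param samples list of >= 2 [tree_sample()] objects (post-burnin).
#' @param min_freq inclusion threshold.
#' @param taxa reference taxon ordering.
#' @return the ASDSF (a single number).
#' @export
asdsf <- function(samples, min_freq = 0.10, taxa = NULL) {
  if (length(samples) < 2) stop("ASDSF needs at least two runs")
  if (is.null(taxa)) taxa <- sort(samples[[1]]$trees[[1]]$tip.label)
  tabs <- lapply(samples, function(s) split_table(s$trees, taxa))
  keys <- unique(unlist(lapply(tabs, `[[`, "key")))
  if (length(keys) == 0) return(0)
  freq <- vapply(tabs, function(tb) {
    f <- tb$freq[match(keys, tb$key)]
    ifelse(is.na(f), 0, f)
  }, numeric(length(keys)))
  freq <- matrix(freq, nrow = length(keys))
  qual <- apply(freq, 1, max) >= min_freq
  if (!any(qual)) return(0)
  mean(apply(freq[qual, , drop = FALSE], 1, stats::sd))
}

#' Run a full multi-run Bayesian analysis
#'
#' Runs `n_runs` independent chains, removes burn-in, and reports per-run
#' harmonic-mean log-likelihoods together with the final cross-run ASDSF; the
#' run with the highest harmonic-mean log-likelihood is flagged.
#'
#' @param matrix a [character_matrix()].
#' @param spec an [mk_model_spec()].
#' @param config an [mcmc_config()].
#' @return list with `samples` (all draws, per run), `post` (post-burnin
#'   samples), `report` (data.frame: run, seed, harmonic_mean_lnL, selected),
#'   `asdsf`, `converged`, `selected`.
#' @export
run_analysis <- function(matrix, spec, config) {
  samples <- lapply(seq_len(config$n_runs), function(i)
    run_chain(matrix, spec, config, run_id = i))
  post <- lapply(samples, discard_burnin, fraction = config$burnin_fraction)
  hm <- vapply(post, harmonic_mean_lnL, 0)
  a <- if (config$n_runs >= 2)
    asdsf(post, config$asdsf_min_freq, taxa = matrix$taxa) else NA_real_
  selected <- which.max(hm)
  report <- data.frame(run = seq_len(config$n_runs), seed = config$seeds,
                       harmonic_mean_lnL = hm,
                       selected = seq_len(config$n_runs) == selected)
  list(samples = samples, post = post, report = report, asdsf = a,
       converged = !is.na(a) && a < config$asdsf_threshold, selected = selected)
}
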