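# Posterior summaries: majority-rule consensus with posterior probabilities,
# harmonic-mean marginal likelihoods and Bayes factors, and monophyly
# hypothesis testing with branch-length-corrected clade credibility.

#' Majority-rule consensus with posterior probabilities
#'
#' Contains exactly the splits whose frequency in the pooled post-burnin
#' sample is strictly greater than 0.5 (such splits are pairwise compatible),
#' each labeled with its frequency; internal branch lengths are the mean over
#' trees containing the split, terminal branch lengths the mean over all
#' trees.
#'
#' @param trees pooled post-burnin trees (`multiPhylo`, list, or
#'   [tree_sample()]).
#' @param taxa reference taxon ordering.
#' @return an `ape::phylo` with `node.label` holding the split frequencies.
#' @export
majority_consensus <- function(trees, taxa = NULL) {
  if (inherits(trees, "tree_sample")) trees <- trees$trees
  if (length(trees) == 0) stop("empty tree sample")
  if (is.null(taxa)) taxa <- sort(trees[[1]]$tip.label)
  st <- split_table(trees, taxa)
  keep <- st$freq > 0.5
  tip_len <- .mean_tip_lengths(trees, taxa)
  .tree_from_splits(attr(st, "sides")[keep], taxa,
                    labels = sprintf("%.4f", st$freq[keep]),
                    lengths = st$mean_length[keep],
                    tip_lengths = tip_len)
}

.mean_tip_lengths <- function(trees, taxa) {
  tot <- numeric(length(taxa)); cnt <- numeric(length(taxa))
  for (tr in trees) {
    if (is.null(tr$edge.length)) next
    ntip <- length(tr$tip.label)
    idx <- match(tr$tip.label, taxa)
    tip_edges <- tr$edge[, 2] <= ntip
    tot[idx[tr$edge[tip_edges, 2]]] <- tot[idx[tr$edge[tip_edges, 2]]] +
      tr$edge.length[tip_edges]
    cnt[idx] <- cnt[idx] + 1
  }
  ifelse(cnt > 0, tot / cnt, NA)
}

#' Posterior probability of monophyly for a taxon set
#'
#' The fraction of post-burnin trees in which the taxon set forms a clade
#' after rooting on the outgroup, together with the posterior-mean length of
#' the clade's subtending branch expressed in expected character changes
#' (per-character branch length times the number of included characters).
#'
#' @param samples a [tree_sample()], list of them, or `multiPhylo` of
#'   post-burnin trees.
#' @param taxon_set character vector of at least two tip labels.
#' @param outgroup tip label used to root the trees; must not be in
#'   `taxon_set`.
#' @param n_chars number of included characters, used to convert the
#'   subtending branch length to expected changes (`NA` to skip).
#' @param taxa reference taxon ordering.
#' @return list with `pp`, `n_samples`, `count`, `branch_length_changes`.
#' @export
monophyly_pp <- function(samples, taxon_set, outgroup, n_chars = NA,
                         taxa = NULL) {
  trees <- .pool_trees(samples)
  if (is.null(taxa)) taxa <- sort(trees[[1]]$tip.label)
  tips <- trees[[1]]$tip.label
  if (!all(taxon_set %in% tips))
    stop("taxon set is not a subset of the sampled trees' tips")
  if (outgroup %in% taxon_set) stop("outgroup cannot be inside the tested clade")
  if (length(taxon_set) < 2) stop("a monophyly test needs >= 2 taxa")
  n <- length(trees)
  # taxon_set is a rooted clade iff the unrooted split {set | rest} exists
  # (rest contains the outgroup); the set of all non-outgroup tips is always
  # a clade (trivial split).
  if (setequal(taxon_set, setdiff(tips, outgroup))) {
    return(list(pp = 1, n_samples = n, count = n,
                branch_length_changes = NA_real_))
  }
  st <- split_table(trees, taxa)
  key <- .set_key(taxon_set, taxa, tips)
  hit <- match(key, st$key)
  count <- if (is.na(hit)) 0L else st$count[hit]
  mean_len <- if (is.na(hit)) NA_real_ else st$mean_length[hit]
  list(pp = count / n, n_samples = n, count = count,
       branch_length_changes = if (is.na(n_chars)) NA_real_ else mean_len * n_chars)
}

.pool_trees <- function(samples) {
  if (inherits(samples, "tree_sample")) return(samples$trees)
  if (inherits(samples, "phylo")) return(list(samples))
  if (length(samples) > 0 && inherits(samples[[1]], "tree_sample")) {
    trees <- do.call(c, lapply(samples, `[[`, "trees"))
    class(trees) <- "multiPhylo"
    return(trees)
  }
  samples
}

#' Harmonic-mean log marginal likelihood
#'
#' The log of the harmonic mean of the sampled likelihoods, computed stably
#' in log space: `-(logsumexp(-lnL) - log(n))`.
#'
#' @param sample a [tree_sample()] or numeric vector of log-likelihoods.
#' @return the harmonic-mean log-likelihood.
#' @export
harmonic_mean_lnL <- function(sample) {
  lnL <- if (inherits(sample, "tree_sample")) sample$lnL else as.numeric(sample)
  if (length(lnL) == 0) stop("empty sample")
  -( .logsumexp(-lnL) - log(length(lnL)) )
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bayes factor on the 2 ln scale
#'
#' `B = 2lnL(b) - 2lnL(a)` where the inputs are twice the (harmonic-mean)
#' log marginal likelihoods of the two models; positive values favor model
#' `b`. The verdict bands follow the conventional 2-ln-scale reading, with
#' values above 10 read as strong support.
#'
#' @param two_lnL_a twice the log marginal likelihood of the reference model.
#' @param two_lnL_b same for the candidate model.
#' @return an object of class `model_comparison`: `two_lnL_a`, `two_lnL_b`,
#'   `B`, `verdict`.
#' @export
bayes_factor <- function(two_lnL_a, two_lnL_b) {
  stopifnot(is.finite(two_lnL_a), is.finite(two_lnL_b))
  B <- two_lnL_b - two_lnL_a
  aB <- abs(B)
  verdict <- if (aB <= 2) "not worth more than a bare mention"
    else if (aB <= 6) "positive"
    else if (aB <= 10) "substantial"
    else "strong"
  structure(list(two_lnL_a = two_lnL_a, two_lnL_b = two_lnL_b, B = B,
                 verdict = verdict),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Bayes factor (2 ln scale): %g [%s]\n", x$B, x$verdict))
  invisible(x)
}

#' Default branch-length correction table for clade credibility
#'
#' A conservative synthetic stand-in for a published minimum-PP-by-branch-
#' length lookup: below 35 expected changes posterior probabilities are known
#' to be liberal, so the minimum PP for 95% credibility rises as the
#' subtending branch shortens (values above 1 mark lengths at which no PP is
#' credible). Users with the original table should supply it instead.
#'
#' @return data.frame with columns `min_changes` (lower bound of the branch
#'   length band) and `min_pp` (nonincreasing with length).
#' @export
default_zander_table <- function() {
  data.frame(
    min_changes = c(0, 5, 10, 15, 20, 25, 30),
    min_pp = c(1.01, 0.9999, 0.999, 0.998, 0.997, 0.995, 0.99)
  )
}

#' Branch-length-corrected clade credibility verdict
#'
#' Posterior probabilities on short branches (fewer than 35 expected
#' character changes) are predictably liberal; this applies a monotone lookup
#' of the minimum PP deemed 95% credible at a given subtending branch length.
#' At or above 35 changes the uncorrected 0.95 rule applies.
#'
#' @param pp posterior probability in `[0, 1]`.
#' @param branch_length_changes subtending branch length in expected
#'   character changes (summed over characters).
#' @param table lookup as in [default_zander_table()] (must be nonincreasing
#'   in `min_pp` as `min_changes` grows).
#' @return `"credible_95"` or `"not_credible_95"`.
#' @export
zander_correct <- function(pp, branch_length_changes,
                           table = default_zander_table()) {
  stopifnot(pp >= 0, pp <= 1, branch_length_changes >= 0)
  o <- order(table$min_changes)
  table <- table[o, ]
  if (is.unsorted(rev(table$min_pp)))
    stop("malformed correction table: min_pp must not increase with branch length")
  if (branch_length_changes >= 35)
    return(if (pp >= 0.95) "credible_95" else "not_credible_95")
  band <- findInterval(branch_length_changes, table$min_changes)
  if (band == 0) return("not_credible_95")
  if (pp >= table$min_pp[band]) "credible_95" else "not_credible_95"
}

#' Battery of monophyly hypothesis tests
#'
#' One test per named taxon set: posterior probability of monophyly (with
#' optional "wild" taxa pruned from every sampled tree before testing),
#' subtending branch length in expected changes, and the corrected
#' credibility verdict. Clades absent from the sample are reported as
#' `"<1/n"` rather than zero.
#'
#' @param samples post-burnin trees ([tree_sample()], list of them, or
#'   `multiPhylo`).
#' @param hypotheses data.frame with columns `name`, `taxa` (semicolon-
#'   separated tip labels) and optional `wild` (semicolon-separated).
#' @param outgroup rooting taxon.
#' @param n_chars number of included characters (for the branch-length
#'   conversion).
#' @param table correction lookup (see [zander_correct()]).
#' @return data.frame: `hypothesis`, `pp`, `pp_report`, `branch_length`,
#'   `verdict`.
#' @export
hypothesis_battery <- function(samples, hypotheses, outgroup, n_chars = NA,
                               table = default_zander_table()) {
  trees <- .pool_trees(samples)
  taxa <- sort(trees[[1]]$tip.label)
  out <- lapply(seq_len(nrow(hypotheses)), function(i) {
    set <- strsplit(hypotheses$taxa[i], ";")[[1]]
    wild <- if ("wild" %in% names(hypotheses) && !is.na(hypotheses$wild[i]) &&
                nzchar(hypotheses$wild[i]))
      strsplit(hypotheses$wild[i], ";")[[1]] else character(0)
    use_trees <- trees
    if (length(wild) > 0) {
      use_trees <- lapply(trees, ape::drop.tip, tip = wild)
      class(use_trees) <- "multiPhylo"
      set <- setdiff(set, wild)
    }
    mp <- monophyly_pp(use_trees, set, outgroup, n_chars, taxa = taxa)
    pp_report <- if (mp$count == 0)
      sprintf("<%.6g", 1 / mp$n_samples) else sprintf("%.6g", mp$pp)
    verdict <- if (!is.na(mp$branch_length_changes))
      zander_correct(mp$pp, mp$branch_length_changes, table) else NA_character_
    data.frame(hypothesis = hypotheses$name[i], pp = mp$pp,
               pp_report = pp_report,
               branch_length = mp$branch_length_changes,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a hypotheses file
#'
#' TSV with columns `name`, `taxa` (semicolon-separated) and optional `wild`.
#'
#' @param path TSV path.
#' @return data.frame suitable for [hypothesis_battery()].
#' @export
read_hypotheses <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
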