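# Ordered posterior draws: trees plus aligned log-likelihood and gamma-shape
# traces, written as paired tab-separated ".t"/".p"-style files.

#' Construct a tree sample
#'
#' @param trees a `multiPhylo` (or list of `phylo`) of sampled topologies with
#'   branch lengths in expected changes per character.
#' @param lnL numeric log-likelihoods, one per draw (finite).
#' @param alpha numeric gamma-shape values, one per draw (`NA` when the model
#'   has no rate variation).
#' @param cycles integer MCMC cycle numbers, strictly increasing.
#' @param run_id identifier of the generating run.
#' @return an object of class `tree_sample`.
#' @export
tree_sample <- function(trees, lnL, alpha = rep(NA_real_, length(lnL)),
                        cycles = seq_along(lnL) - 1L, run_id = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  n <- length(trees)
  stopifnot(length(lnL) == n, length(alpha) == n, length(cycles) == n)
  if (n > 0) {
    if (any(!is.finite(lnL))) stop("lnL must be finite")
    if (any(diff(cycles) <= 0)) stop("cycle numbers must be strictly increasing")
  }
  structure(list(trees = trees, lnL = as.numeric(lnL),
                 alpha = as.numeric(alpha), cycles = as.integer(cycles),
                 run_id = run_id),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("tree_sample: %d draws (run %s)\n", length(x$lnL), x$run_id))
  invisible(x)
}

#' Number of draws in a tree sample
#' @param sample a [tree_sample()].
#' @return integer draw count.
#' @export
n_draws <- function(sample) length(sample$lnL)

#' Draws recorded by a chain of given length
#'
#' A draw is taken at the start of every `sample_every`-cycle block (cycles 0,
#' `sample_every`, 2`sample_every`, ...), so a chain of `c * sample_every`
#' cycles yields `c` draws and a zero-cycle chain yields the start state only.
#'
#' @param cycles total chain length in cycles.
#' @param sample_every sampling interval in cycles.
#' @return integer number of recorded draws.
#' @export
expected_draws <- function(cycles, sample_every) {
  stopifnot(sample_every >= 1, cycles >= 0)
  max(1L, as.integer(ceiling(cycles / sample_every)))
}

#' Remove the burn-in portion of a sample
#'
#' @param sample a [tree_sample()].
#' @param fraction proportion in `[0, 1)`; the first `floor(fraction * n)`
#'   draws are removed.
#' @return the truncated `tree_sample`.
#' @export
discard_burnin <- function(sample, fraction) {
  stopifnot(inherits(sample, "tree_sample"), fraction >= 0, fraction < 1)
  n <- n_draws(sample)
  drop <- floor(fraction * n)
  keep <- setdiff(seq_len(n), seq_len(drop))
  tree_sample(sample$trees[keep], sample$lnL[keep], sample$alpha[keep],
              sample$cycles[keep], sample$run_id)
}

#' Write a tree sample to paired .t/.p files
#'
#' `<prefix>.t` holds one Newick tree per draw (named by cycle);
#' `<prefix>.p` is tab-separated with header `cycle lnL alpha`.
#'
#' @param sample a [tree_sample()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_tree_sample <- function(sample, prefix) {
  stopifnot(inherits(sample, "tree_sample"))
  n <- n_draws(sample)
  tlines <- vapply(seq_len(n), function(i) {
    sprintf("tree cycle_%d = %s", sample$cycles[i],
            ape::write.tree(sample$trees[[i]], digits = 12))
  }, "")
  writeLines(tlines, paste0(prefix, ".t"))
  plines <- c("cycle\tlnL\talpha",
              vapply(seq_len(n), function(i) {
                sprintf("%d\t%.10g\t%.10g", sample$cycles[i], sample$lnL[i],
                        sample$alpha[i])
              }, ""))
  writeLines(plines, paste0(prefix, ".p"))
  invisible(prefix)
}

#' Read a tree sample from paired .t/.p files
#'
#' @param prefix path prefix as used by [write_tree_sample()].
#' @param run_id identifier to attach to the sample.
#' @return a [tree_sample()]; cycle numbers in the two files must agree.
#' @export
read_tree_sample <- function(prefix, run_id = 1L) {
  tpath <- paste0(prefix, ".t")
  ppath <- paste0(prefix, ".p")
  if (!file.exists(tpath) || !file.exists(ppath))
    stop(sprintf("missing sample files for prefix '%s'", prefix))
  tlines <- readLines(tpath, warn = FALSE)
  tlines <- tlines[nzchar(trimws(tlines))]
  tcycles <- as.integer(sub("^tree cycle_(\\d+) = .*$", "\\1", tlines))
  newicks <- sub("^tree cycle_\\d+ = ", "", tlines)
  trees <- lapply(newicks, function(s) ape::read.tree(text = s))
  p <- utils::read.table(ppath, header = TRUE, sep = "\t",
                         col.names = c("cycle", "lnL", "alpha"))
  if (nrow(p) != length(trees) ||
      (nrow(p) > 0 && any(p$cycle != tcycles)))
    stop("cycle mismatch between .t and .p files")
  tree_sample(trees, p$lnL, p$alpha, p$cycle, run_id)
}
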