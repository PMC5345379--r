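test_that("sampling arithmetic matches the every-100-cycles rule", {
  expect_equal(expected_draws(8e6, 100), 80000L)
  expect_equal(expected_draws(0, 100), 1L)
  expect_equal(expected_draws(150, 100), 2L)
})

test_that("a zero-cycle chain returns the start state only", {
  fx <- fixture_matrix(n_taxa = 5, n_chars = 8, seed = 1)
  s <- run_chain(fx$matrix, mk_model_spec(),
                 mcmc_config(cycles = 0, sample_every = 1, n_runs = 1, seed = 4))
  expect_equal(n_draws(s), 1L)
  expect_equal(s$cycles, 0L)
})

test_that("chains are bit-reproducible given a seed", {
  fx <- fixture_matrix(n_taxa = 6, n_chars = 12, seed = 2)
  cfg <- mcmc_config(cycles = 400, sample_every = 40, n_runs = 1, seed = 77)
  s1 <- run_chain(fx$matrix, mk_model_spec(), cfg)
  s2 <- run_chain(fx$matrix, mk_model_spec(), cfg)
  expect_identical(s1$lnL, s2$lnL)
  expect_identical(ape::write.tree(s1$trees), ape::write.tree(s2$trees))
})

test_that("MCMC refuses fewer than four taxa", {
  fx <- fixture_matrix(n_taxa = 5, n_chars = 6, seed = 3)
  m <- fx$matrix
  m$cells <- m$cells[1:3, ]
  m$taxa <- m$taxa[1:3]
  expect_error(run_chain(m, mk_model_spec(),
                         mcmc_config(cycles = 10, sample_every = 10, seed = 1)),
               ">= 4 taxa")
})

test_that("prior-only sampling matches the exponential prior and uniform topologies", {
  fx <- fixture_matrix(n_taxa = 4, n_chars = 6, seed = 5)
  cfg <- mcmc_config(cycles = 120000, sample_every = 20, n_runs = 1, seed = 9,
                     sample_prior = TRUE)
  s <- discard_burnin(run_chain(fx$matrix, mk_model_spec(), cfg), 0.25)
  bl <- unlist(lapply(s$trees, function(t) t$edge.length))
  # thin to weaken autocorrelation before the KS test
  thin <- bl[seq(1, length(bl), by = 25)]
  expect_gt(stats::ks.test(thin, "pexp", rate = 10)$p.value, 0.01)
  topo <- vapply(s$trees, function(t)
    paste(sort(morphoclade:::.tree_splits(t, fx$matrix$taxa)$keys), collapse = "|"), "")
  counts <- table(topo)
  expect_equal(length(counts), 3L)
  # binomial 3-sigma band around 1/3 with an effective sample size that
  # accounts for autocorrelation (conservative: n/25)
  n_eff <- length(topo) / 25
  for (p in counts / length(topo))
    expect_lt(abs(p - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n_eff))
})

test_that("with fixed branch lengths the sampler matches the exact 3-topology posterior", {
  # 4 taxa, all branch lengths equal: the chain reduces to a 3-state sampler
  # whose exact posterior is computable by direct likelihood evaluation
  taxa <- c("A", "B", "C", "D")
  set.seed(6)
  tr_true <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  m <- simulate_matrix(tr_true, sim_config(n_taxa = 4, n_chars = 120, seed = 31,
                                           alpha_true = NA,
                                           k_probs = c("2" = 1)))
  spec <- mk_model_spec()
  newicks <- c("((A:0.1,B:0.1):0.1,C:0.1,D:0.1);",
               "((A:0.1,C:0.1):0.1,B:0.1,D:0.1);",
               "((A:0.1,D:0.1):0.1,B:0.1,C:0.1);")
  lls <- vapply(newicks, function(s)
    matrix_loglik(ape::read.tree(text = s), m, spec), 0, USE.NAMES = FALSE)
  exact <- exp(lls - max(lls)); exact <- exact / sum(exact)
  cfg <- mcmc_config(cycles = 60000, sample_every = 10, n_runs = 1, seed = 13,
                     weights = c(nni = 1, blen = 0, alpha = 0))
  s <- run_chain(m, spec, cfg)
  # force-start effects: drop burnin
  s <- discard_burnin(s, 0.25)
  keyify <- function(t) paste(sort(morphoclade:::.tree_splits(t, taxa)$keys),
                              collapse = "|")
  keys3 <- vapply(newicks, function(x) keyify(ape::read.tree(text = x)), "",
                  USE.NAMES = FALSE)
  topo <- vapply(s$trees, keyify, "")
  freq <- vapply(keys3, function(k) mean(topo == k), 0)
  # NNI-induced lengths stay equal, so frequencies should track `exact`
  n_eff <- length(topo) / 20
  for (i in 1:3)
    expect_lt(abs(freq[i] - exact[i]),
              3 * sqrt(max(exact[i] * (1 - exact[i]), 1e-4) / n_eff) + 0.02)
  expect_equal(unname(which.max(freq)), unname(which.max(exact)))
})

test_that("ASDSF follows its definition and hand-computed example", {
  t_ab <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  t_ac <- ape::read.tree(text = "((A:1,C:1):1,B:1,D:1);")
  mk_sample <- function(trees, id) tree_sample(trees, rep(-1, length(trees)),
                                               cycles = seq_along(trees) - 1L,
                                               run_id = id)
  sA <- mk_sample(rep(list(t_ab), 10), 1)
  sB <- mk_sample(c(rep(list(t_ab), 8), rep(list(t_ac), 2)), 2)
  expect_equal(asdsf(list(sA, sA)), 0)
  got <- asdsf(list(sA, sB), min_freq = 0.1)
  # split AB|CD at 1.0 vs 0.8 (sd .1414); split AC|BD at 0 vs 0.2 (sd .1414)
  expect_equal(got, stats::sd(c(1, 0.8)), tolerance = 1e-12)
  expect_error(asdsf(list(sA)), "two runs")
})

test_that("independent runs converge on a strong-signal fixture", {
  set.seed(8)
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.3,(C:0.1,D:0.1):0.3);")
  m <- simulate_matrix(tr, sim_config(n_taxa = 4, n_chars = 200, seed = 17,
                                      alpha_true = NA, k_probs = c("2" = 1)))
  cfg <- mcmc_config(cycles = 20000, sample_every = 20, n_runs = 2, seed = 21)
  res <- run_analysis(m, mk_model_spec(), cfg)
  expect_lt(res$asdsf, 0.05)
  # modal sampled topology is the generating topology
  topo <- vapply(res$post[[1]]$trees, function(t)
    paste(sort(morphoclade:::.tree_splits(t, m$taxa)$keys), collapse = "|"), "")
  true_key <- paste(sort(morphoclade:::.tree_splits(ape::unroot(tr), m$taxa)$keys),
                    collapse = "|")
  expect_equal(names(sort(table(topo), decreasing = TRUE))[1], true_key)
})

test_that("run_analysis selects the replicate with highest harmonic-mean lnL", {
  fx <- fixture_matrix(n_taxa = 5, n_chars = 10, seed = 9)
  cfg <- mcmc_config(cycles = 2000, sample_every = 100, n_runs = 3, seed = 33)
  res <- run_analysis(fx$matrix, mk_model_spec(), cfg)
  hm <- vapply(res$post, harmonic_mean_lnL, 0)
  expect_equal(res$selected, which.max(hm))
  expect_equal(res$report$harmonic_mean_lnL, hm)
  expect_equal(sum(res$report$selected), 1L)
})

test_that("identical per-run seeds give identical samples and zero ASDSF", {
  fx <- fixture_matrix(n_taxa = 5, n_chars = 10, seed = 10)
  cfg <- mcmc_config(cycles = 1500, sample_every = 100, n_runs = 2, seed = 3,
                     seeds = c(3L, 3L))
  res <- run_analysis(fx$matrix, mk_model_spec(), cfg)
  expect_identical(ape::write.tree(res$samples[[1]]$trees),
                   ape::write.tree(res$samples[[2]]$trees))
  expect_equal(res$asdsf, 0)
})
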