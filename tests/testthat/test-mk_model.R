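test_that("rate matrices are normalized to one expected change per unit length", {
  expect_equal(rate_matrix(2), matrix(c(-1, 1, 1, -1), 2, 2))
  for (k in 2:5) for (ord in c(FALSE, TRUE)) {
    Q <- rate_matrix(k, ord)
    expect_equal(rowSums(Q), rep(0, k), tolerance = 1e-12)
    expect_equal(sum(-diag(Q)) / k, 1, tolerance = 1e-12)  # uniform pi
    expect_equal(Q, t(Q))
  }
  Q3 <- rate_matrix(3, ordered = TRUE)
  expect_equal(Q3[1, 3], 0)
  expect_equal(Q3[3, 1], 0)
  expect_error(rate_matrix(1), "k >= 2")
})

test_that("transition probabilities match the closed form and limits", {
  expect_equal(transition_probs(rate_matrix(3), 0), diag(3))
  P <- transition_probs(rate_matrix(2), 0.1)
  expect_equal(P[1, 1], 0.5 + 0.5 * exp(-0.2), tolerance = 1e-12)
  for (k in 2:4) {
    nu <- 0.37
    P <- transition_probs(rate_matrix(k), nu)
    expect_equal(diag(P), rep(1 / k + (k - 1) / k * exp(-nu * k / (k - 1)), k),
                 tolerance = 1e-12)
    expect_equal(rowSums(P), rep(1, k), tolerance = 1e-12)
    Pinf <- transition_probs(rate_matrix(k), 100)
    expect_equal(as.vector(Pinf), rep(1 / k, k * k), tolerance = 1e-9)
  }
  expect_error(transition_probs(rate_matrix(2), -0.1), "negative")
})

test_that("gamma discretization has mean 1 and collapses at large shape", {
  for (a in c(0.2, 0.5, 1, 5)) {
    r <- gamma_category_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
    rm_ <- gamma_category_rates(a, 4, method = "median")
    expect_equal(mean(rm_), 1, tolerance = 1e-12)
  }
  expect_equal(gamma_category_rates(1e6, 4), rep(1, 4), tolerance = 1e-2)
})

test_that("single-taxon column has stationary likelihood", {
  tr <- ape::read.tree(text = "(A:0.3);")
  ll <- character_loglik(tr, c(A = 1L), character_meta(2),
                         mk_model_spec(conditioning = "all"))
  expect_equal(ll$lnL, -log(2), tolerance = 1e-12)
})

test_that("pruning equals enumeration on trees up to 5 taxa", {
  specs <- list(
    list(k = 2, ordered = FALSE, gamma = FALSE),
    list(k = 3, ordered = FALSE, gamma = FALSE),
    list(k = 3, ordered = TRUE, gamma = FALSE),
    list(k = 2, ordered = FALSE, gamma = TRUE),
    list(k = 3, ordered = TRUE, gamma = TRUE)
  )
  set.seed(31)
  for (n in 3:5) {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$tip.label <- LETTERS[1:n]
    for (sp in specs) {
      k <- sp$k
      masks <- sample(seq_len(2^k - 1), n, replace = TRUE)
      masks[1] <- 1L  # keep at least one observed cell (all-missing errors)
      names(masks) <- tr$tip.label
      rates <- if (sp$gamma) gamma_category_rates(0.5, 4) else 1
      for (cond in c("all", "variable")) {
        oracle <- brute_column_loglik(tr, unname(masks)[match(tr$tip.label, names(masks))],
                                      k, sp$ordered, rates, cond)
        spec <- mk_model_spec(gamma = sp$gamma, alpha = 0.5, conditioning = cond)
        got <- character_loglik(tr, masks,
                                character_meta(k, ordered = sp$ordered), spec)
        val <- if (cond == "variable") got$corrected else got$lnL
        expect_equal(val, oracle, tolerance = 1e-9)
      }
    }
  }
})

test_that("corrected likelihoods of all variable patterns sum to one", {
  for (n in 3:4) {
    set.seed(n)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$tip.label <- LETTERS[1:n]
    for (k in 2:3) for (gam in c(FALSE, TRUE)) {
      spec <- mk_model_spec(gamma = gam, alpha = 0.7, conditioning = "variable")
      meta <- character_meta(k)
      total <- 0
      grid <- do.call(expand.grid, rep(list(seq_len(k) - 1L), n))
      for (g in seq_len(nrow(grid))) {
        states <- as.integer(grid[g, ])
        if (length(unique(states)) == 1) next
        col <- bitwShiftL(1L, states)
        names(col) <- tr$tip.label
        total <- total + exp(character_loglik(tr, col, meta, spec)$corrected)
      }
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  set.seed(5)
  for (rep in 1:3) {
    fx <- fixture_matrix(n_taxa = 7, n_chars = 12, seed = rep,
                         missing_rate = 0.1, polymorphism_rate = 0.05)
    tr <- ape::unroot(fx$tree)
    spec <- mk_model_spec(gamma = TRUE, alpha = 0.8)
    base <- matrix_loglik(tr, fx$matrix, spec)
    for (og in c(2, 5)) {
      rerooted <- ape::root(tr, outgroup = tr$tip.label[og], resolve.root = FALSE)
      expect_equal(matrix_loglik(rerooted, fx$matrix, spec), base,
                   tolerance = 1e-9)
    }
  }
})

test_that("large gamma shape converges to the no-gamma likelihood", {
  fx <- fixture_matrix(n_taxa = 8, n_chars = 15, seed = 12)
  l0 <- matrix_loglik(fx$tree, fx$matrix, mk_model_spec(gamma = FALSE))
  l1 <- matrix_loglik(fx$tree, fx$matrix, mk_model_spec(gamma = TRUE, alpha = 1e6))
  expect_lt(abs(l1 - l0), 1e-6)
})

test_that("adding missing data never decreases a character's likelihood", {
  set.seed(21)
  fx <- fixture_matrix(n_taxa = 6, n_chars = 8, seed = 3,
                       missing_rate = 0, polymorphism_rate = 0)
  m <- fx$matrix
  spec <- mk_model_spec(conditioning = "all")
  for (j in seq_len(8)) {
    col <- m$cells[, j]
    names(col) <- m$taxa
    base <- character_loglik(fx$tree, col, m$meta[j, , drop = FALSE], spec)$lnL
    i <- sample(length(col), 1)
    col2 <- col
    col2[i] <- .Machine$integer.max  # replaced below with full set
    col2[i] <- bitwShiftL(1L, m$meta$k[j]) - 1L
    more <- character_loglik(fx$tree, col2, m$meta[j, , drop = FALSE], spec)$lnL
    expect_gte(more + 1e-12, base)
  }
})

test_that("matrix likelihood decomposes over characters and duplicates add", {
  fx <- fixture_matrix(n_taxa = 6, n_chars = 10, seed = 13)
  m <- fx$matrix
  spec <- mk_model_spec(gamma = TRUE, alpha = 0.5)
  res <- matrix_loglik(fx$tree, m, spec, per_character = TRUE)
  singles <- vapply(seq_len(10), function(j) {
    col <- m$cells[, j]; names(col) <- m$taxa
    character_loglik(fx$tree, col, m$meta[j, , drop = FALSE], spec)$corrected
  }, 0)
  expect_equal(res$total, sum(singles), tolerance = 1e-9)
  expect_equal(res$per_char$corrected, singles, tolerance = 1e-9)
  # duplicating a column doubles its contribution
  m2 <- character_matrix(cbind(m$cells, m$cells[, 1]), m$taxa,
                         character_meta(c(m$meta$k, m$meta$k[1]),
                                        ordered = c(m$meta$ordered, m$meta$ordered[1])))
  expect_equal(matrix_loglik(fx$tree, m2, spec),
               res$total + singles[1], tolerance = 1e-9)
})

test_that("empty and all-missing inputs follow the error contract", {
  fx <- fixture_matrix(n_taxa = 5, n_chars = 4, seed = 14)
  empty <- character_matrix(matrix(integer(0), 5, 0), fx$matrix$taxa,
                            character_meta(integer(0)))
  expect_equal(matrix_loglik(fx$tree, empty, mk_model_spec()), 0)
  m <- fx$matrix
  m$cells[, 2] <- .full_mask_for_test(m$meta$k[2])
  expect_error(matrix_loglik(fx$tree, m, mk_model_spec(conditioning = "variable")),
               "entirely missing")
  expect_silent(matrix_loglik(fx$tree, m, mk_model_spec(conditioning = "all")))
})

test_that("likelihood report carries per-character terms", {
  fx <- fixture_matrix(n_taxa = 5, n_chars = 6, seed = 15)
  f <- withr::local_tempfile(fileext = ".tsv")
  spec <- mk_model_spec()
  rep_df <- write_likelihood_report(fx$tree, fx$matrix, spec, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 6L)
  expect_true(all(back$correction >= 0))
})
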