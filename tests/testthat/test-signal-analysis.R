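# Decisive sites, Fisher contingency tests, gene outlier scans and
# parsimony summaries.

test_that("decisive sites: degenerate, seeded spike and antisymmetry", {
  # equal differences: sd = 0, nothing decisive
  d0 <- decisive_sites(rep(2, 10), rep(1, 10))
  expect_equal(d0$n_a + d0$n_b, 0)

  set.seed(101)
  b <- rnorm(1000)
  a <- b + rnorm(1000)        # delta ~ N(0, 1)
  a[417] <- b[417] + 100
  rep5 <- decisive_sites(a, b, m = 5)
  expect_equal(rep5$decisive_a, 417L)
  expect_equal(rep5$n_b, 0)

  # negating the inputs swaps the two decisive sets exactly
  swapped <- decisive_sites(b, a, m = 5)
  expect_equal(swapped$decisive_b, rep5$decisive_a)
  expect_equal(swapped$decisive_a, rep5$decisive_b)

  # adding a constant to every delta leaves mean-centred counts unchanged
  shift <- decisive_sites(a + 7, b, m = 5)
  expect_equal(shift$n_a, rep5$n_a)
  expect_equal(shift$n_b, rep5$n_b)

  expect_error(decisive_sites(1, 1:2), "shape error")
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE),
                                "greater"), 1 / 252, tolerance = 1e-12)
  # zero margin: only one table is possible
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE),
                                "greater"), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "domain error")

  set.seed(55)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    tab <- matrix(stats::rmultinom(1, n, runif(4, 0.05, 1)), 2)
    expect_equal(fisher_exact_2x2(tab, "greater"),
                 brute_fisher_greater(tab), tolerance = 1e-10)
  }
})

test_that("gene outlier flags reproduce the three-fold rule", {
  # the published flagging fixture: one gene towers over the rest
  deltas <- c(106.63, 28.67, 9.39, 15.2, 22.1, -12.4)
  expect_equal(flag_outlier_genes(deltas, 3),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any(flag_outlier_genes(rep(5, 4), 3)))
})

test_that("an against-the-grain gene is the extreme outlier end to end", {
  t2 <- default_metazoan_tree("T2", 2)
  t3 <- default_metazoan_tree("T3", 2)
  mod <- substitution_model("LG", alpha = 0.9)
  sim_gene <- function(tree, seed, len)
    simulate_alignment(simulation_config(
      tree = tree, exposed_model = mod, buried_model = mod,
      exposed_rate_multiplier = 1, n_genes = 1, gene_length = len,
      exposed_fraction = 1, missing_fraction = 0.1,
      seed = seed))$alignment$matrix
  blocks <- c(lapply(1:4, function(g) sim_gene(t2, g, 120)),
              list(sim_gene(t3, 5, 360)))
  m <- do.call(cbind, blocks)
  ends <- cumsum(vapply(blocks, ncol, 0L))
  gm <- data.frame(gene = paste0("g", 1:5),
                   start = c(1L, head(ends, -1) + 1L), end = ends)
  al <- alignment(m, gene_map = gm)
  scan <- gene_outlier_scan(al, t2, t3, mod, fold_threshold = 2)
  expect_equal(which.max(abs(scan$delta_lnl)), 5L)
  expect_lt(scan$delta_lnl[5], 0)          # it favours the other topology
  expect_gt(min(scan$delta_lnl[1:4]), 0)
})

test_that("Fitch steps match exhaustive labelling; informativeness rule", {
  tr_ab <- parse_tree("((t1,t2),(t3,t4));")
  tr_ax <- parse_tree("((t1,t3),(t2,t4));")
  col_aabb <- alignment(matrix(c("A", "A", "R", "R"), 4, 1,
                               dimnames = list(paste0("t", 1:4), NULL)))
  p1 <- parsimony_summary(col_aabb, tr_ab)$per_character
  expect_equal(p1[, c("s_obs", "s_min", "s_max")],
               data.frame(s_obs = 1L, s_min = 1L, s_max = 2L))
  expect_true(p1$informative)
  p2 <- parsimony_summary(col_aabb, tr_ax)$per_character
  expect_equal(p2$s_obs, 2L)

  # constant characters have zero steps and are excluded from the RI
  m3 <- matrix(c("A", "A", "R", "R",
                 "A", "A", "R", "R",
                 "C", "C", "C", "C"), 4, 3,
               dimnames = list(paste0("t", 1:4), NULL))
  ps <- parsimony_summary(alignment(m3), tr_ab)
  expect_equal(ps$per_character$s_obs, c(1L, 1L, 0L))
  expect_false(ps$per_character$informative[3])
  expect_equal(ps$retention_index, 1.0)

  # randomized exhaustive oracle on 5-6 leaf trees with missing data
  set.seed(66)
  for (rep in 1:12) {
    n <- sample(5:6, 1)
    tr <- ape::rtopology(n, rooted = FALSE,
                         tip.label = paste0("t", 1:n))
    al <- random_alignment(n, 4, "STATE6", missing_frac = 0.2)
    got <- parsimony_summary(al, tr)$per_character$s_obs
    sidx <- structphylo:::state_index_matrix(al)[tr$tip.label, ]
    want <- vapply(seq_len(ncol(sidx)), function(j)
      brute_fitch_steps(sidx[, j], tr, 6), 0)
    expect_equal(got, as.integer(want))
  }
})

test_that("parsimony agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(91)
  tr <- ape::rtopology(7, rooted = FALSE, tip.label = paste0("t", 1:7))
  al <- random_alignment(7, 40, "AA20")
  got <- sum(parsimony_summary(al, tr)$per_character$s_obs)
  pd <- phangorn::phyDat(al$matrix, type = "AA")
  expect_equal(got, phangorn::parsimony(tr, pd))
})
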