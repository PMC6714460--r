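test_that("hypergeometric tails match direct enumeration of draws", {
  # frozen from the combinatorial count: P(X = 0) = C(5,4)/C(10,4) = 5/210
  r <- hypergeometric_overlap_test(10, 5, 4, 0, "depletion")
  expect_equal(r$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(r$p_value, oracle_hyper_enum(10, 5, 4, 0, "depletion"),
               tolerance = 1e-12)

  # spot enumeration over every subset for a few small configurations
  for (cfg in list(c(8, 3, 4), c(9, 5, 3), c(10, 6, 5))) {
    G <- cfg[1]; K <- cfg[2]; n <- cfg[3]
    for (k in max(0, K + n - G):min(K, n)) {
      expect_equal(hypergeometric_overlap_test(G, K, n, k,
                                               "depletion")$p_value,
                   oracle_hyper_enum(G, K, n, k, "depletion"),
                   tolerance = 1e-12)
      expect_equal(hypergeometric_overlap_test(G, K, n, k,
                                               "enrichment")$p_value,
                   oracle_hyper_enum(G, K, n, k, "enrichment"),
                   tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric boundary cases and feasibility checks hold", {
  expect_equal(hypergeometric_overlap_test(10, 5, 4, 4,
                                           "depletion")$p_value, 1)
  r0 <- hypergeometric_overlap_test(10, 5, 0, 0, "depletion")
  expect_equal(r0$p_value, 1)
  expect_equal(hypergeometric_overlap_test(10, 5, 0, 0,
                                           "enrichment")$p_value, 1)
  expect_error(hypergeometric_overlap_test(10, 5, 4, 5), "infeasible")
  expect_error(hypergeometric_overlap_test(10, 12, 4, 2), "infeasible")
  expect_error(hypergeometric_overlap_test(10, 8, 8, 2), "infeasible")

  # complementary tails partition the support; pmf sums to 1
  for (i in 1:20) {
    set.seed(i)
    G <- sample(5:60, 1); K <- sample(0:G, 1); n <- sample(0:G, 1)
    lo <- max(0, K + n - G); hi <- min(K, n)
    pmf <- stats::dhyper(lo:hi, K, G - K, n)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    for (k in lo:hi) {
      dep <- hypergeometric_overlap_test(G, K, n, k, "depletion")$p_value
      enr <- if (k < hi)
        hypergeometric_overlap_test(G, K, n, k + 1, "enrichment")$p_value
      else 0
      expect_equal(dep + enr, 1, tolerance = 1e-10)
    }
  }
})

test_that("rank comparison matches enumeration and applies the skip rule", {
  # A = {1,2}, B = {3,4}: only one of C(4,2) = 6 assignments is as low
  r <- rank_score_comparison(c(1, 2), c(3, 4), min_n = 2,
                             alternative = "less")
  expect_equal(r$p_value, 1 / 6, tolerance = 1e-12)
  expect_equal(r$p_value, oracle_ranksum(c(1, 2), c(3, 4), "less"))

  same <- rank_score_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$performed)
  expect_equal(same$p_value, 1)

  skip_case <- rank_score_comparison(1, c(1, 2, 3), min_n = 3)
  expect_false(skip_case$performed)
  expect_identical(skip_case$reason, "too few data")
  expect_true(is.na(skip_case$p_value))

  expect_error(rank_score_comparison(c(1, Inf), c(1, 2)), "finite")
  expect_error(rank_score_comparison(1:3, 1:4, paired = TRUE), "paired")
})

test_that("significance stars follow the conventional thresholds", {
  expect_identical(significance_stars(c(0.2, 0.04, 1e-6, 1e-11, NA)),
                   c("ns", "*", "**", "***", NA))
})

test_that("standardized degree follows the percentage formula", {
  path <- graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(degree_pct(path)), c(50, 100, 50))
  k5 <- graph_from_adjacency(matrix(1, 5, 5) - diag(5))
  expect_equal(unname(degree_pct(k5)), rep(100, 5))

  set.seed(2)
  for (i in 1:10) {
    adj <- random_adjacency(sample(5:15, 1), 0.4)
    g <- graph_from_adjacency(adj)
    expect_equal(unname(degree_pct(g)),
                 rowSums(adj) / (nrow(adj) - 1) * 100)
  }
})

test_that("normalized betweenness matches geodesic enumeration", {
  path <- graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(betweenness_norm(path)), c(0, 1, 0))
  star <- graph_from_adjacency(
    rbind(c(0, 1, 1, 1, 1), cbind(1, matrix(0, 4, 4))))
  expect_equal(unname(betweenness_norm(star)), c(1, 0, 0, 0, 0))

  set.seed(4)
  for (i in 1:15) {
    adj <- random_adjacency(sample(5:12, 1), 0.35)
    g <- graph_from_adjacency(adj)
    oracle <- oracle_centrality(adj)
    expect_equal(unname(betweenness_norm(g)), oracle$betweenness_norm,
                 tolerance = 1e-9)
  }
})

test_that("graph construction thresholds weights and keeps isolated nodes", {
  ed <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                   weight = c(0.9, 0.4, 0.6), stringsAsFactors = FALSE)
  gd <- mirhostnet:::new_tissue_graph_data("heart", c("A", "B", "C", "D"),
                                           ed)
  g_all <- build_graph(gd, weight_threshold = 0)
  expect_identical(igraph::ecount(g_all), 3)
  g_half <- build_graph(gd, weight_threshold = 0.5)
  expect_identical(igraph::ecount(g_half), 2)
  expect_identical(igraph::vcount(g_half), 4)
  expect_equal(unname(degree_pct(g_half)["D"]), 0)
  g_none <- build_graph(gd, weight_threshold = 2)
  expect_identical(igraph::ecount(g_none), 0)
  expect_identical(igraph::vcount(g_none), 4)
})

test_that("centrality comparison handles planted, identical and empty groups", {
  scn <- small_scenario(seed = 21L, centrality_bias = 5)
  av <- generate_association_vector(scn, "cardiac_muscle")
  pred <- generate_target_predictions(scn, av)
  tu <- union(pred[[1L]]$targets, pred[[2L]]$targets)
  gd <- generate_tissue_graph(scn, "cardiac_muscle", av, tu)
  prof <- centrality_profile(build_graph(gd, weight_threshold = 0))
  cmp <- compare_target_centrality(prof, tu, intersect(tu, av$associated))
  expect_true(cmp$degree$performed)
  expect_lt(cmp$degree$p_value, 0.05)

  ident <- compare_target_centrality(prof, tu, tu,
                                     alternative = "two.sided")
  expect_equal(ident$degree$p_value, 1)

  none <- compare_target_centrality(prof, tu, character())
  expect_false(none$degree$performed)
  expect_false(none$betweenness$performed)
})
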