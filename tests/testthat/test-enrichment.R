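coll_of <- function(...) {
  sets <- list(...)
  mirhostnet:::new_gene_set_collection(lapply(seq_along(sets), function(i)
    list(name = paste0("S", i), description = "", members = sets[[i]])))
}

test_that("over-representation p-values are exact hypergeometric tails", {
  universe <- sprintf("U%03d", 1:100)
  set10 <- universe[1:10]
  r <- overrepresentation_test(set10, coll_of(set10), universe)
  expect_equal(r$p_nominal, 1 / choose(100, 10), tolerance = 1e-12)
  expect_identical(r$overlap_count, 10L)

  # universe 20, set of 5, query of 4, overlap 2 -> P(X >= 2) by
  # enumeration of every C(20,4) draw
  u20 <- sprintf("U%03d", 1:20)
  r2 <- overrepresentation_test(c(u20[1:2], u20[6:7]),
                                coll_of(u20[1:5]), u20)
  expect_equal(r2$p_nominal, oracle_hyper_enum(20, 5, 4, 2, "enrichment"),
               tolerance = 1e-12)

  disjoint <- overrepresentation_test(u20[11:14], coll_of(u20[1:5]), u20)
  expect_equal(disjoint$p_nominal, 1)
  expect_identical(disjoint$overlap_count, 0L)

  expect_error(overrepresentation_test(character(), coll_of(u20[1:5]), u20),
               "empty query")
  expect_error(overrepresentation_test(u20[1:3], coll_of(u20[1:5]),
                                       character()), "empty universe")
  expect_warning(
    overrepresentation_test(c(u20[1:3], "NOT_THERE"), coll_of(u20[1:5]),
                            u20), "outside the universe")
})

test_that("over-representation p-values are invariant under gene relabelling", {
  set.seed(12)
  universe <- sprintf("U%03d", 1:50)
  for (i in 1:10) {
    s1 <- sample(universe, 12)
    s2 <- sample(universe, 8)
    q <- sample(universe, 10)
    r <- overrepresentation_test(q, coll_of(s1, s2), universe)
    relabel <- stats::setNames(sample(sprintf("V%03d", 1:50)), universe)
    r2 <- overrepresentation_test(unname(relabel[q]),
                                  coll_of(unname(relabel[s1]),
                                          unname(relabel[s2])),
                                  unname(relabel))
    expect_equal(sort(r$p_nominal), sort(r2$p_nominal))
    expect_equal(sort(r$fdr_q), sort(r2$fdr_q))
  }
})

test_that("running-sum enrichment score matches the brute-force walk", {
  scores <- c(A = 5, B = 4, C = 3, D = 2, E = 1)
  head1 <- preranked_es(scores, "A", weight_exponent = 0)
  expect_equal(head1$es, 1)
  # single member at the list tail: four misses of -1/4 then the hit
  tail1 <- preranked_es(scores, "E", weight_exponent = 0)
  expect_equal(tail1$es, -1)
  expect_equal(tail1$es, oracle_es(scores, "E", p = 0))
  expect_equal(tail1$running_sum, cumsum(c(rep(-0.25, 4), 1)))

  expect_error(preranked_es(scores, c("X", "Y")), "no gene-set member")
  expect_error(preranked_es(scores, names(scores)), "entire ranked list")

  set.seed(9)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    s <- stats::rnorm(n)
    names(s) <- sprintf("G%03d", seq_len(n))
    set <- sample(names(s), sample(2:(n - 2), 1))
    for (p in c(0, 1)) {
      es <- preranked_es(s, set, weight_exponent = p)$es
      expect_equal(es, oracle_es(s, set, p = p), tolerance = 1e-12)
      expect_gte(es, -1); expect_lte(es, 1)
    }
  }
})

test_that("enrichment score agrees with an independent implementation", {
  set.seed(31)
  s <- sort(stats::rnorm(60), decreasing = TRUE)
  names(s) <- sprintf("G%03d", 1:60)
  for (i in 1:10) {
    idx <- sort(sample(60, sample(3:15, 1)))
    es <- preranked_es(s, names(s)[idx], weight_exponent = 1)$es
    expect_equal(es, fgsea::calcGseaStat(unname(s), idx, gseaParam = 1),
                 tolerance = 1e-9)
  }
})

test_that("reversing the ranked list flips the unweighted enrichment score", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    s <- stats::rnorm(n)
    names(s) <- sprintf("G%03d", seq_len(n))
    set <- sample(names(s), 5)
    r <- preranked_es(s, set, weight_exponent = 0)
    rv <- preranked_es(-s, set, weight_exponent = 0)
    expect_equal(abs(rv$es), abs(r$es), tolerance = 1e-12)
    # the sign flips whenever the extreme deviation is unique in magnitude
    if (abs(max(r$running_sum)) != abs(min(r$running_sum)))
      expect_equal(rv$es, -r$es, tolerance = 1e-12)
  }
})

test_that("preranked significance is deterministic and flags the planted set", {
  set.seed(40)
  n <- 120
  s <- sort(stats::runif(n), decreasing = TRUE)
  names(s) <- sprintf("G%03d", seq_len(n))
  planted <- names(s)[1:12]
  coll <- coll_of(planted, sample(names(s), 15), sample(names(s), 10),
                  sample(names(s), 20))
  r1 <- preranked_significance(s, coll, n_perm = 300, seed = 5)
  r2 <- preranked_significance(s, coll, n_perm = 300, seed = 5)
  expect_identical(r1, r2)
  expect_identical(r1$set_name[1L], "S1")
  expect_lt(r1$fdr_q[1L], min(r1$fdr_q[-1L]) + 1e-12)
  expect_true(all(r1$es >= -1 & r1$es <= 1, na.rm = TRUE))

  expect_error(preranked_significance(s, coll, n_perm = 5), "at least 10")
  expect_warning(preranked_significance(s, coll, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("Benjamini-Hochberg step-up matches the hand-computed example", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  # q is monotone in p after sorting and never below p
  set.seed(6)
  for (i in 1:10) {
    p <- stats::runif(30)
    q <- benjamini_hochberg(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
  }
})
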