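test_that("association vector plants an exact associated count with a disjoint mixture", {
  scn <- small_scenario(n_genes = 1000L, assoc_fraction = 0.1)
  av <- generate_association_vector(scn, "cardiac_muscle")
  expect_length(av$scores, 999L)
  expect_false(scn$host_gene %in% names(av$scores))
  # rounding rule: round(0.1 * 999) half away from zero = 100
  expect_length(av$associated, 100L)
  expect_true(all(av$scores[av$associated] > scn$assoc_threshold))
  expect_true(all(av$scores[setdiff(names(av$scores), av$associated)] <
                    scn$assoc_threshold))

  none <- generate_association_vector(small_scenario(assoc_fraction = 0),
                                      "cardiac_muscle")
  expect_length(none$associated, 0L)
  expect_true(all(none$scores < scn$assoc_threshold))
})

test_that("generators are deterministic in seed and parameters", {
  scn <- small_scenario()
  a1 <- generate_association_vector(scn, "skin")
  a2 <- generate_association_vector(scn, "skin")
  expect_identical(a1, a2)
  expect_false(identical(
    a1$scores, generate_association_vector(scn, "cardiac_muscle")$scores))
  p1 <- generate_target_predictions(scn)
  p2 <- generate_target_predictions(scn)
  expect_identical(p1, p2)
  g1 <- generate_tissue_graph(scn, "skin")
  g2 <- generate_tissue_graph(scn, "skin")
  expect_identical(g1, g2)
})

test_that("unknown tissue and infeasible parameters are configuration errors", {
  scn <- small_scenario()
  expect_error(generate_association_vector(scn, "liver"), "unknown tissue")
  expect_error(generate_tissue_graph(scn, "liver"), "unknown tissue")
  expect_error(small_scenario(n_targets_per_predictor = 300L),
               "n_targets_per_predictor")
  # union of two size-200 sets with no overlap cannot fit in 299 genes
  expect_error(small_scenario(n_targets_per_predictor = 160L,
                              predictor_overlap = 0),
               "infeasible predictor_overlap")
  expect_error(small_scenario(centrality_bias = 0.5), "centrality_bias")
  expect_error(small_scenario(assoc_fraction = 1.2), "assoc_fraction")
})

test_that("predictor overlap and association bias shape the target draw", {
  scn <- small_scenario(predictor_overlap = 1)
  pred <- generate_target_predictions(scn)
  expect_identical(pred[[1L]]$targets, pred[[2L]]$targets)
  expect_identical(pred[[1L]]$source, "TargetScan")
  expect_identical(pred[[2L]]$source, "miRDB")

  scn0 <- small_scenario(target_assoc_bias = 0)
  av <- generate_association_vector(scn0, "cardiac_muscle")
  pred0 <- generate_target_predictions(scn0, av)
  union0 <- union(pred0[[1L]]$targets, pred0[[2L]]$targets)
  expect_length(intersect(union0, av$associated), 0L)

  half <- small_scenario(predictor_overlap = 0.5)
  ph <- generate_target_predictions(half)
  expect_length(intersect(ph[[1L]]$targets, ph[[2L]]$targets), 20L)
  expect_false(half$host_gene %in% union(ph[[1L]]$targets,
                                         ph[[2L]]$targets))
})

test_that("unbiased target sampling matches the universe association rate", {
  # Monte-Carlo over many seeds: with bias 1 the expected fraction of
  # associated genes among targets is K / (n_genes - 1)
  reps <- 1000L
  fracs <- vapply(seq_len(reps), function(i) {
    scn <- small_scenario(seed = i, target_assoc_bias = 1)
    av <- generate_association_vector(scn, "cardiac_muscle")
    pred <- generate_target_predictions(scn, av)
    mean(pred[[1L]]$targets %in% av$associated)
  }, numeric(1L))
  expected <- 30 / 299
  se <- stats::sd(fracs) / sqrt(reps)
  expect_lt(abs(mean(fracs) - expected), 3 * se)
})

test_that("tissue graph density and planted centrality behave as configured", {
  empty <- generate_tissue_graph(small_scenario(edge_density = 0),
                                 "cardiac_muscle")
  expect_identical(nrow(empty$edges), 0L)

  gd <- generate_tissue_graph(small_scenario(edge_density = 0.05), "skin")
  n_pairs <- choose(300, 2)
  expect_gt(nrow(gd$edges), 0.05 * n_pairs * 0.8)
  expect_lt(nrow(gd$edges), 0.05 * n_pairs * 1.2)
  expect_true(all(gd$edges$weight > 0 & gd$edges$weight <= 1))
  expect_true(all(gd$edges$gene_a < gd$edges$gene_b))  # no self loops

  # bias 1: hot-node mean degree matches universe mean within 3 SE of the
  # across-seed differences
  diffs <- vapply(seq_len(200L), function(i) {
    scn <- small_scenario(seed = i, centrality_bias = 1)
    av <- generate_association_vector(scn, "cardiac_muscle")
    pred <- generate_target_predictions(scn, av)
    tu <- union(pred[[1L]]$targets, pred[[2L]]$targets)
    gd <- generate_tissue_graph(scn, "cardiac_muscle", av, tu)
    hot <- intersect(tu, av$associated)
    if (!length(hot)) return(NA_real_)
    g <- build_graph(gd, weight_threshold = 0)
    d <- igraph::degree(g)
    mean(d[hot]) - mean(d)
  }, numeric(1L))
  diffs <- diffs[!is.na(diffs)]
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))

  # strong bias: hot nodes are strictly more connected in nearly all seeds
  hits <- vapply(seq_len(100L), function(i) {
    scn <- small_scenario(seed = i, centrality_bias = 5)
    av <- generate_association_vector(scn, "cardiac_muscle")
    pred <- generate_target_predictions(scn, av)
    tu <- union(pred[[1L]]$targets, pred[[2L]]$targets)
    gd <- generate_tissue_graph(scn, "cardiac_muscle", av, tu)
    hot <- intersect(tu, av$associated)
    g <- build_graph(gd, weight_threshold = 0)
    d <- igraph::degree(g)
    mean(d[hot]) > mean(d)
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("gene-set generator plants the designated overlap", {
  top <- sprintf("G%05d", 1:20)
  scn <- small_scenario(planted_set_overlap = 15L)
  coll <- generate_gene_set_collection(scn, top)
  expect_length(coll, 20L)
  planted <- coll[[1L]]
  expect_identical(planted$name, "SET_PLANTED")
  expect_length(intersect(planted$members, top), 15L)
  expect_true(all(top[1:15] %in% planted$members))

  full <- generate_gene_set_collection(
    small_scenario(planted_set_overlap = 20L), top)
  expect_true(all(top %in% full[[1L]]$members))

  none <- generate_gene_set_collection(
    small_scenario(planted_set_overlap = 0L), character())
  expect_length(none, 20L)
  expect_error(generate_gene_set_collection(scn, top[1:5]),
               "planted_set_overlap")
})

test_that("simulate_scenario writes a complete, self-consistent bundle", {
  dir <- withr::local_tempdir()
  scn <- small_scenario(planted_set_overlap = 0L)
  paths <- simulate_scenario(scn, dir)
  expect_true(all(file.exists(unlist(paths))))
  truth <- jsonlite::read_json(paths$ground_truth, simplifyVector = TRUE)
  av <- read_association_table(paths$assoc_cardiac_muscle,
                               scn$host_gene, "cardiac_muscle")
  crit <- association_criterion(scn$assoc_threshold, "above")
  expect_identical(host_associated_genes(av, crit),
                   sort(truth$associated$cardiac_muscle))
  tt <- read_target_table(paths$targets_targetscan)
  expect_identical(tt$targets, sort(truth$targets$TargetScan))
})
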