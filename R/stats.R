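#' Hypergeometric overlap test
#'
#' Tests whether the overlap `k` between a target set of size `n` and the
#' host-associated set of size `K`, drawn from a universe of `G` genes,
#' is smaller (depletion), larger (enrichment) or different (two-sided)
#' than expected under random sampling without replacement. Tail
#' probabilities come from the hypergeometric distribution, evaluated in
#' log space and exponentiated so that extreme tails remain accurate.
#'
#' @param G Universe size.
#' @param K Number of host-associated genes in the universe.
#' @param n Number of targets drawn.
#' @param k Observed overlap.
#' @param alternative `"depletion"` (`P(X <= k)`), `"enrichment"`
#'   (`P(X >= k)`), or `"two.sided"` (double the smaller tail, capped at
#'   1).
#' @return An `overlap_test` object with the counts, the alternative and
#'   `p_value`.
#' @export
hypergeometric_overlap_test <- function(G, K, n, k,
                                        alternative = c("depletion",
                                                        "enrichment",
                                                        "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(G) == 1L, length(K) == 1L, length(n) == 1L,
            length(k) == 1L)
  G <- as.integer(G); K <- as.integer(K); n <- as.integer(n)
  k <- as.integer(k)
  if (G < 0L || K < 0L || n < 0L || K > G || n > G)
    stop("infeasible counts: need 0 <= K, n <= G", call. = FALSE)
  if (k < max(0L, K + n - G) || k > min(K, n))
    stop("infeasible overlap k = ", k, ": support is [",
         max(0L, K + n - G), ", ", min(K, n), "]", call. = FALSE)
  p_dep <- exp(stats::phyper(k, K, G - K, n, lower.tail = TRUE,
                             log.p = TRUE))
  p_enr <- exp(stats::phyper(k - 1L, K, G - K, n, lower.tail = FALSE,
                             log.p = TRUE))
  p <- switch(alternative,
              depletion = p_dep,
              enrichment = p_enr,
              two.sided = min(1, 2 * min(p_dep, p_enr)))
  structure(list(universe_size = G, associated_count = K,
                 target_count = n, overlap = k,
                 expected_overlap = n * K / max(G, 1L),
                 alternative = alternative, p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0("Hypergeometric overlap test (%s): k = %d, ",
                     "expected = %.2f (G = %d, K = %d, n = %d), ",
                     "p = %.4g\n"),
              x$alternative, x$overlap, x$expected_overlap,
              x$universe_size, x$associated_count, x$target_count,
              x$p_value))
  invisible(x)
}

#' Significance stars at the conventional thresholds
#'
#' `"*"` for p < 0.05, `"**"` for p < 1e-5, `"***"` for p < 1e-10,
#' `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 1e-5] <- "**"
  out[p < 1e-10] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Rank-based comparison of two score groups
#'
#' Compares two groups of scores (e.g. fractional ranks of filtered
#' targets vs. all host-associated genes, or centralities of
#' host-interacting targets vs. all targets) with a two-sample rank-sum
#' (Mann-Whitney) test: the exact null is used when both groups have at
#' most 10 observations and there are no ties, the tie-corrected normal
#' approximation otherwise. When either group is smaller than `min_n`
#' no test is performed and the reason is recorded — mirroring analyses
#' that skip comparisons when too few data are available. A paired
#' signed-rank mode is available but refuses unequal group lengths.
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @param min_n Minimum group size for a test to be attempted.
#' @param alternative `"two.sided"`, `"greater"` (A tends larger than B)
#'   or `"less"`.
#' @param paired Use the paired signed-rank test (requires equal
#'   lengths).
#' @return A `rank_comparison` object: group sizes, `performed`,
#'   `statistic`, `p_value`, `stars`, `reason` when skipped.
#' @export
rank_score_comparison <- function(scores_a, scores_b, min_n = 3L,
                                  alternative = c("two.sided", "greater",
                                                  "less"),
                                  paired = FALSE) {
  alternative <- match.arg(alternative)
  if (!all(is.finite(scores_a)) || !all(is.finite(scores_b)))
    stop("scores must be finite", call. = FALSE)
  na <- length(scores_a); nb <- length(scores_b)
  if (paired && na != nb)
    stop("paired mode requires equal group lengths (", na, " vs ", nb, ")",
         call. = FALSE)
  if (min(na, nb) < min_n) {
    return(structure(list(group_a_size = na, group_b_size = nb,
                          performed = FALSE, statistic = NA_real_,
                          p_value = NA_real_, stars = NA_character_,
                          alternative = alternative,
                          reason = "too few data"),
                     class = "rank_comparison"))
  }
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0L
  exact <- !paired && na <= 10L && nb <= 10L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, alternative = alternative,
                       paired = paired, exact = exact, correct = TRUE))
  structure(list(group_a_size = na, group_b_size = nb, performed = TRUE,
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 stars = significance_stars(wt$p.value),
                 alternative = alternative, reason = NA_character_),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  if (!x$performed)
    cat("Rank comparison not performed (", x$reason, "); sizes ",
        x$group_a_size, " vs ", x$group_b_size, "\n", sep = "")
  else
    cat(sprintf("Rank comparison (%s): W = %g, p = %.4g %s (n = %d vs %d)\n",
                x$alternative, x$statistic, x$p_value, x$stars,
                x$group_a_size, x$group_b_size))
  invisible(x)
}

#' Build an unweighted simple graph for centrality analysis
#'
#' Keeps edges with weight at or above `weight_threshold` and returns an
#' undirected simple igraph over the full node universe — genes without
#' surviving edges stay as isolated nodes with degree 0.
#'
#' @param graph_data A `tissue_graph_data` (edge list plus node
#'   universe).
#' @param weight_threshold Minimum edge weight retained.
#' @return An igraph object with the tissue stored as a graph attribute.
#' @export
build_graph <- function(graph_data, weight_threshold = 0.5) {
  stopifnot(inherits(graph_data, "tissue_graph_data"))
  edges <- graph_data$edges
  edges <- edges[edges$weight >= weight_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = graph_data$nodes,
                          stringsAsFactors = FALSE))
  g <- igraph::simplify(g)
  g <- igraph::set_graph_attr(g, "tissue", graph_data$tissue)
  igraph::set_graph_attr(g, "weight_threshold", weight_threshold)
}

#' Standardized degree centrality
#'
#' Degree divided by the maximum possible degree `|V| - 1`, expressed as
#' a percentage in `[0, 100]`.
#'
#' @param graph An igraph object.
#' @return Named numeric vector over all nodes.
#' @export
degree_pct <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L) return(stats::setNames(numeric(n), igraph::V(graph)$name))
  igraph::degree(graph) / (n - 1L) * 100
}

#' Normalized betweenness centrality
#'
#' Shortest-path betweenness with even splitting among equal-length
#' geodesics, normalized by `(|V| - 1)(|V| - 2) / 2` (undirected) to
#' `[0, 1]`. Edge weights are ignored: the graph is treated as the
#' unweighted interaction skeleton.
#'
#' @param graph An igraph object.
#' @return Named numeric vector over all nodes.
#' @export
betweenness_norm <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 3L) return(stats::setNames(numeric(n), igraph::V(graph)$name))
  igraph::betweenness(graph, directed = FALSE, weights = NA,
                      normalized = TRUE)
}

#' Centrality profile of a tissue graph
#'
#' @param graph An igraph object from [build_graph()].
#' @return A `centrality_profile`: `tissue`, `degree_pct`,
#'   `betweenness_norm` (both named over all nodes).
#' @export
centrality_profile <- function(graph) {
  structure(list(tissue = igraph::graph_attr(graph, "tissue"),
                 degree_pct = degree_pct(graph),
                 betweenness_norm = betweenness_norm(graph)),
            class = "centrality_profile")
}

#' Compare centrality of host-interacting targets with all targets
#'
#' Tests whether the targets that are functionally associated with the
#' host gene occupy more central network positions than the full
#' predicted target set, separately for standardized degree and
#' normalized betweenness. One-sided ("interacting greater") by default.
#' Targets absent from the graph's node set are dropped; isolated nodes
#' participate with centrality 0.
#'
#' @param profile A [centrality_profile()].
#' @param all_targets Character vector: every predicted target.
#' @param interacting_targets Character vector: targets associated with
#'   the host gene in this tissue.
#' @param min_n Minimum group size, as in [rank_score_comparison()].
#' @param alternative Test direction, default `"greater"`.
#' @return List with elements `degree` and `betweenness`, each a
#'   `rank_comparison`.
#' @export
compare_target_centrality <- function(profile, all_targets,
                                      interacting_targets, min_n = 3L,
                                      alternative = "greater") {
  stopifnot(inherits(profile, "centrality_profile"))
  nodes <- names(profile$degree_pct)
  at <- intersect(all_targets, nodes)
  it <- intersect(interacting_targets, nodes)
  list(
    degree = rank_score_comparison(profile$degree_pct[it],
                                   profile$degree_pct[at],
                                   min_n = min_n,
                                   alternative = alternative),
    betweenness = rank_score_comparison(profile$betweenness_norm[it],
                                        profile$betweenness_norm[at],
                                        min_n = min_n,
                                        alternative = alternative))
}
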