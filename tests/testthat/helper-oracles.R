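# Independent brute-force oracles used to pin down the statistical
# contracts. These stay deliberately naive: closed-form counting for the
# hypergeometric tails, full enumeration of rank assignments for the
# rank-sum test, explicit geodesic enumeration for centrality, and a
# direct running-sum walk for the enrichment score.

# hypergeometric tail by summing the counting-formula pmf
oracle_hyper <- function(G, K, n, k, alternative) {
  j <- seq(max(0, K + n - G), min(K, n))
  pmf <- choose(K, j) * choose(G - K, n - j) / choose(G, n)
  switch(alternative,
         depletion = sum(pmf[j <= k]),
         enrichment = sum(pmf[j >= k]))
}

# same tail by enumerating every possible draw of n genes from G
# (feasible only for small G)
oracle_hyper_enum <- function(G, K, n, k, alternative) {
  draws <- utils::combn(G, n)
  overlaps <- apply(draws, 2, function(d) sum(d <= K))
  switch(alternative,
         depletion = mean(overlaps <= k),
         enrichment = mean(overlaps >= k))
}

# exact rank-sum p-value by enumerating all C(na+nb, na) rank assignments;
# two-sided doubles the smaller tail as wilcox.test's exact branch does
oracle_ranksum <- function(a, b, alternative) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_null <- apply(combos, 2, function(ix) sum(ix) - na * (na + 1) / 2)
  switch(alternative,
         greater = mean(u_null >= u_obs),
         less = mean(u_null <= u_obs),
         two.sided = {
           if (u_obs > na * nb / 2) min(1, 2 * mean(u_null >= u_obs))
           else min(1, 2 * mean(u_null <= u_obs))
         })
}

# standardized degree and normalized betweenness by BFS distances plus
# depth-limited enumeration of every geodesic
oracle_centrality <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  btw <- rep(0, n)
  dist_from <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      for (u in which(adj[v, ] > 0))
        if (is.infinite(d[u])) { d[u] <- d[v] + 1; q <- c(q, u) }
    }
    d
  }
  D <- t(vapply(seq_len(n), dist_from, numeric(n)))
  for (s in seq_len(max(0, n - 1))) for (t in seq(s + 1, n)) {
    if (s + 1 > n) break
    d <- D[s, t]
    if (!is.finite(d) || d == 0) next
    sigma <- 0; through <- rep(0, n)
    rec <- function(v, visited, len) {
      if (v == t) {
        if (len == d) {
          sigma <<- sigma + 1
          interior <- setdiff(visited, c(s, t))
          through[interior] <<- through[interior] + 1
        }
        return(invisible(NULL))
      }
      if (len >= d) return(invisible(NULL))
      for (u in which(adj[v, ] > 0))
        if (!(u %in% visited)) rec(u, c(visited, u), len + 1L)
    }
    rec(s, s, 0L)
    if (sigma > 0) btw <- btw + through / sigma
  }
  list(degree_pct = deg / (n - 1) * 100,
       betweenness_norm = if (n > 2) btw / ((n - 1) * (n - 2) / 2)
                          else rep(0, n))
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p]
  adj[on] <- 1L
  adj + t(adj)
}

graph_from_adjacency <- function(adj) {
  nm <- sprintf("N%02d", seq_len(nrow(adj)))
  ix <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(gene_a = nm[ix[, 1L]], gene_b = nm[ix[, 2L]],
                      weight = 1, stringsAsFactors = FALSE)
  gd <- mirhostnet:::new_tissue_graph_data("test", nm, edges)
  build_graph(gd, weight_threshold = 0)
}

# direct running-sum walk down the full ranked list
oracle_es <- function(scores, set, p = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% set
  w <- abs(s)^p
  W <- sum(w[hit])
  inc <- ifelse(hit, w / W, -1 / sum(!hit))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# small scenario used across tests; individual tests override fields
small_scenario <- function(...) {
  args <- list(n_genes = 300L, tissues = c("cardiac_muscle", "skin"),
               assoc_fraction = 0.1, n_targets_per_predictor = 40L,
               predictor_overlap = 0.5, edge_density = 0.05,
               n_gene_sets = 20L, gene_set_size_range = c(5L, 20L),
               seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(synthetic_scenario, args)
}
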