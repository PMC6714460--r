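#' Over-representation test of a gene list against a collection
#'
#' For each gene set, tests whether the overlap with the query list is
#' larger than expected when drawing `|query|` genes from the universe
#' (one-sided hypergeometric enrichment tail), then adjusts across all
#' tested sets with the Benjamini-Hochberg step-up procedure. This is the
#' overlap computation behind gene-set databases' "investigate gene list"
#' utilities, appropriate for an unranked top-target list.
#'
#' @param query Character vector of query genes (e.g. the top filtered
#'   targets).
#' @param collection A `gene_set_collection`.
#' @param universe Character vector of background genes. Query genes
#'   outside the universe are dropped with a warning; set members outside
#'   the universe do not count.
#' @param include_zero_overlap Report sets with zero overlap (p = 1)
#'   rather than dropping them.
#' @return An `enrichment_result` data.frame: `set_name`, `description`,
#'   `overlap_count`, `set_size`, `p_nominal`, `fdr_q`, sorted by `fdr_q`
#'   then `set_name`.
#' @export
overrepresentation_test <- function(query, collection, universe,
                                    include_zero_overlap = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(toupper(query))
  if (!length(query)) stop("empty query", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
    if (!length(query)) stop("no query gene in the universe", call. = FALSE)
  }
  G <- length(universe); nq <- length(query)
  res <- do.call(rbind, lapply(collection, function(s) {
    members <- intersect(s$members, universe)
    Ks <- length(members)
    k <- length(intersect(members, query))
    p <- if (Ks == 0L) 1 else
      exp(stats::phyper(k - 1L, Ks, G - Ks, nq, lower.tail = FALSE,
                        log.p = TRUE))
    data.frame(set_name = s$name, description = s$description,
               overlap_count = k, set_size = Ks, p_nominal = p,
               stringsAsFactors = FALSE)
  }))
  if (!include_zero_overlap)
    res <- res[res$overlap_count > 0L, , drop = FALSE]
  res$fdr_q <- benjamini_hochberg(res$p_nominal)
  res <- res[order(res$fdr_q, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Running-sum enrichment score of one gene set
#'
#' Walks down the ranked gene list accumulating `|score|^p / sum(|score|^p)`
#' at gene-set hits and `-1 / (N - N_hits)` at misses; the enrichment
#' score (ES) is the signed maximum deviation of this running sum from
#' zero, in `[-1, 1]`. With `weight_exponent = 0` this is the classic
#' Kolmogorov-Smirnov-style statistic; the default 1 weights hits by
#' their scores.
#'
#' @param ranked_scores Named numeric vector of gene scores; sorted
#'   descending internally (ties broken by gene name for determinism).
#' @param gene_set Character vector of member genes; must intersect the
#'   ranked list.
#' @param weight_exponent Exponent `p` applied to hit scores.
#' @return List with `es`, `running_sum` (length `N` profile) and
#'   `hit_positions`.
#' @export
preranked_es <- function(ranked_scores, gene_set, weight_exponent = 1) {
  stopifnot(is.numeric(ranked_scores), !is.null(names(ranked_scores)))
  ord <- order(-ranked_scores, names(ranked_scores))
  s <- ranked_scores[ord]
  hits <- which(names(s) %in% toupper(gene_set))
  N <- length(s)
  if (!length(hits))
    stop("no gene-set member appears in the ranked list", call. = FALSE)
  if (length(hits) == N)
    stop("gene set covers the entire ranked list; ES undefined",
         call. = FALSE)
  w <- abs(s[hits])^weight_exponent
  if (sum(w) == 0) w <- rep(1, length(hits))  # all-zero scores: fall back
  inc <- rep(-1 / (N - length(hits)), N)
  inc[hits] <- w / sum(w)
  rs <- cumsum(inc)
  es <- rs[which.max(abs(rs))]
  list(es = unname(es), running_sum = unname(rs),
       hit_positions = unname(hits))
}

# ES values for one set size k over permuted hit positions, given the
# fixed descending score sequence. Gene-label permutation of scores
# followed by re-ranking is equivalent to placing the k hits uniformly at
# random among the N rank positions, which is what is sampled here.
null_es_for_size <- function(abs_w, k, n_perm) {
  N <- length(abs_w)
  m <- N - k
  vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(N, k))
    w <- abs_w[pos]
    W <- sum(w)
    if (W == 0) { w <- rep(1, k); W <- k }
    tops <- cumsum(w) / W - (pos - seq_len(k)) / m
    bottoms <- tops - w / W
    mx <- max(tops); mn <- min(bottoms)
    if (mx >= -mn) mx else mn
  }, numeric(1L))
}

es_from_positions <- function(abs_w, pos) {
  N <- length(abs_w)
  k <- length(pos)
  w <- abs_w[pos]
  W <- sum(w)
  if (W == 0) { w <- rep(1, k); W <- k }
  tops <- cumsum(w) / W - (pos - seq_len(k)) / (N - k)
  bottoms <- tops - w / W
  mx <- max(tops); mn <- min(bottoms)
  if (mx >= -mn) mx else mn
}

#' Preranked enrichment with a gene-label permutation null
#'
#' Computes the running-sum enrichment score of every set in a
#' collection against a ranked gene list, then assesses significance by
#' permuting the scores over genes (`n_perm` shuffles): the nominal p is
#' the same-sign null tail, the normalized enrichment score (NES) is the
#' ES divided by the mean of same-sign null ES magnitudes, and the FDR q
#' follows the sign-matched NES procedure of classic gene-set enrichment
#' analysis (pooled null NES tail fraction over observed NES tail
#' fraction, capped at 1). Deterministic under a fixed seed.
#'
#' Sets overlapping the ranked list in fewer than `min_hits` genes are
#' reported with `NA` statistics and excluded from the null pool: the
#' ES of a one- or two-gene overlap is too unstable to normalize, and
#' letting such sets into the pooled null corrupts the FDR of every
#' other set (the classic implementation applies a minimum set size for
#' the same reason). Within each sign, q-values are made monotone
#' non-increasing in |NES| by a cumulative minimum, so a stronger
#' normalized score never receives a larger q.
#'
#' @param ranked_scores Named numeric vector of gene scores.
#' @param collection A `gene_set_collection`; sets with fewer than
#'   `min_hits` members in the ranked list are reported with `NA`
#'   statistics.
#' @param n_perm Number of permutations (warning below 100, error below
#'   10).
#' @param seed Integer seed for the permutation stream.
#' @param weight_exponent Exponent on hit scores, as in
#'   [preranked_es()].
#' @param min_hits Minimum number of gene-set members that must appear
#'   in the ranked list for the set to be tested.
#' @return An `enrichment_result` data.frame with additional `es` and
#'   `nes` columns, sorted by `fdr_q` then `set_name`.
#' @export
preranked_significance <- function(ranked_scores, collection,
                                   n_perm = 1000L, seed = 1L,
                                   weight_exponent = 1, min_hits = 5L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 10L) stop("n_perm must be at least 10", call. = FALSE)
  if (n_perm < 100L)
    warning("n_perm < 100 gives coarse p-values", call. = FALSE)
  ord <- order(-ranked_scores, names(ranked_scores))
  s <- ranked_scores[ord]
  abs_w <- abs(s)^weight_exponent
  N <- length(s)
  set.seed(as.integer(seed))

  sizes <- integer(length(collection))
  obs <- rep(NA_real_, length(collection))
  hitpos <- vector("list", length(collection))
  for (i in seq_along(collection)) {
    pos <- which(names(s) %in% collection[[i]]$members)
    sizes[i] <- length(pos)
    if (length(pos) < min_hits || length(pos) == N) next
    hitpos[[i]] <- pos
    obs[i] <- es_from_positions(abs_w, pos)
  }
  # one null ensemble per distinct tested set size, reused across sets
  usizes <- sort(unique(sizes[is.finite(obs)]))
  nulls <- lapply(usizes, function(k) null_es_for_size(abs_w, k, n_perm))
  names(nulls) <- as.character(usizes)

  nes <- p_nom <- rep(NA_real_, length(collection))
  null_nes <- vector("list", length(collection))
  for (i in seq_along(collection)) {
    if (is.na(obs[i])) next
    nul <- nulls[[as.character(sizes[i])]]
    pos_mean <- mean(nul[nul >= 0])
    neg_mean <- mean(abs(nul[nul < 0]))
    if (obs[i] >= 0) {
      same <- nul[nul >= 0]
      p_nom[i] <- (1 + sum(same >= obs[i])) / (1 + length(same))
      nes[i] <- if (is.finite(pos_mean) && pos_mean > 0)
        obs[i] / pos_mean else NA_real_
    } else {
      same <- nul[nul < 0]
      p_nom[i] <- (1 + sum(same <= obs[i])) / (1 + length(same))
      nes[i] <- if (is.finite(neg_mean) && neg_mean > 0)
        obs[i] / neg_mean else NA_real_
    }
    nn <- nul
    nn[nul >= 0] <- if (is.finite(pos_mean) && pos_mean > 0)
      nul[nul >= 0] / pos_mean else NA_real_
    nn[nul < 0] <- if (is.finite(neg_mean) && neg_mean > 0)
      nul[nul < 0] / neg_mean else NA_real_
    null_nes[[i]] <- nn
  }
  pool <- unlist(null_nes[!vapply(null_nes, is.null, logical(1L))])
  pool <- pool[is.finite(pool)]
  obs_nes <- nes[is.finite(nes)]
  fdr <- rep(NA_real_, length(collection))
  for (i in seq_along(collection)) {
    if (!is.finite(nes[i])) next
    if (nes[i] >= 0) {
      denom_pool <- sum(pool >= 0)
      num <- if (denom_pool) sum(pool >= nes[i]) / denom_pool else 1
      denom_obs <- sum(obs_nes >= nes[i]) / max(1L, sum(obs_nes >= 0))
    } else {
      denom_pool <- sum(pool < 0)
      num <- if (denom_pool) sum(pool <= nes[i]) / denom_pool else 1
      denom_obs <- sum(obs_nes <= nes[i]) / max(1L, sum(obs_nes < 0))
    }
    fdr[i] <- min(1, if (denom_obs > 0) num / denom_obs else 1)
  }
  # q-value logic: each set reports the smallest FDR over all rejection
  # regions (NES thresholds of its sign) that contain it, so a stronger
  # |NES| never gets a larger q than a weaker one
  pos_i <- which(is.finite(nes) & nes >= 0)
  pos_i <- pos_i[order(-nes[pos_i])]
  fdr[pos_i] <- rev(cummin(rev(fdr[pos_i])))
  neg_i <- which(is.finite(nes) & nes < 0)
  neg_i <- neg_i[order(nes[neg_i])]
  fdr[neg_i] <- rev(cummin(rev(fdr[neg_i])))
  res <- data.frame(
    set_name = vapply(collection, `[[`, "", "name"),
    description = vapply(collection, `[[`, "", "description"),
    overlap_count = sizes,
    set_size = vapply(collection, function(x) length(x$members),
                      integer(1L)),
    p_nominal = p_nom, fdr_q = fdr, es = obs, nes = nes,
    stringsAsFactors = FALSE)
  res <- res[order(res$fdr_q, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`: q-values are
#' `p * m / rank` with a cumulative minimum applied from the largest
#' rank, capped at 1.
#'
#' @param p_values Numeric vector of p-values.
#' @return Numeric vector of q-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}
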