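#' Generate a tissue association vector
#'
#' Draws one host-gene-centric association score per non-host gene in the
#' universe, from a two-component mixture split at the scenario's
#' association threshold `c`: exactly `round(assoc_fraction * (n_genes -
#' 1))` genes (rounding half away from zero) score in `(c, 1]` and are the
#' ground-truth associated set; every other gene scores in `[0, c)`. The
#' disjoint mixture makes ground-truth membership exact under the
#' criterion "score above `c`".
#'
#' @param scenario A [synthetic_scenario()].
#' @param tissue One of `scenario$tissues`.
#' @return A `tissue_assoc` object: `host_gene`, `tissue`, `scores` (named
#'   numeric over non-host genes), `associated` (ground-truth gene
#'   symbols) and `threshold`.
#' @export
generate_association_vector <- function(scenario, tissue) {
  stopifnot(inherits(scenario, "mirhost_scenario"))
  ti <- match(tissue, scenario$tissues)
  if (is.na(ti))
    stop("unknown tissue '", tissue, "'; scenario tissues are: ",
         paste(scenario$tissues, collapse = ", "), call. = FALSE)
  set.seed(derive_seed(scenario$seed, 1L, ti))
  genes <- scenario$genes[-1L]
  m <- length(genes)
  n_assoc <- round_half_up(scenario$assoc_fraction * m)
  thr <- scenario$assoc_threshold
  associated <- if (n_assoc > 0L) sort(sample(genes, n_assoc)) else character()
  scores <- stats::runif(m, min = 0, max = thr)
  names(scores) <- genes
  if (n_assoc > 0L)
    scores[associated] <- thr + stats::runif(n_assoc) * (1 - thr)
  new_tissue_assoc(host_gene = scenario$host_gene, tissue = tissue,
                   scores = scores, associated = associated,
                   threshold = thr)
}

new_tissue_assoc <- function(host_gene, tissue, scores,
                             associated = NULL, threshold = NA_real_) {
  structure(list(host_gene = host_gene, tissue = tissue, scores = scores,
                 associated = associated, threshold = threshold),
            class = "tissue_assoc")
}

#' @export
print.tissue_assoc <- function(x, ...) {
  cat("Tissue association vector: host", x$host_gene,
      "in", x$tissue, "—", length(x$scores), "genes scored")
  if (!is.null(x$associated))
    cat(";", length(x$associated), "associated (ground truth)")
  cat("\n")
  invisible(x)
}

#' Generate the two predictor target tables
#'
#' Samples the target sets of the two emulated predictors without
#' replacement from the non-host universe. A shared core of
#' `round(predictor_overlap * n_targets_per_predictor)` genes is drawn
#' first and given to both predictors; each predictor is then completed
#' with its own disjoint complement, so the realized shared fraction
#' equals `predictor_overlap` up to rounding. Sampling weights of
#' host-associated genes (ground truth of the scenario's first tissue by
#' default) are multiplied by `target_assoc_bias` and renormalized:
#' bias 1 is a uniform draw, bias 0 excludes associated genes entirely.
#'
#' @param scenario A [synthetic_scenario()].
#' @param assoc Optional `tissue_assoc` supplying the ground-truth labels
#'   the bias is applied against; defaults to the first tissue's vector.
#' @return A list of two `target_table` objects (sources `"TargetScan"`
#'   and `"miRDB"`).
#' @export
generate_target_predictions <- function(scenario, assoc = NULL) {
  stopifnot(inherits(scenario, "mirhost_scenario"))
  if (is.null(assoc))
    assoc <- generate_association_vector(scenario, scenario$tissues[1L])
  stopifnot(inherits(assoc, "tissue_assoc"))
  set.seed(derive_seed(scenario$seed, 2L))
  genes <- scenario$genes[-1L]
  n_t <- scenario$n_targets_per_predictor
  n_shared <- round_half_up(scenario$predictor_overlap * n_t)
  total <- 2L * n_t - n_shared
  w <- rep(1, length(genes))
  w[genes %in% assoc$associated] <- scenario$target_assoc_bias
  if (sum(w > 0) < total)
    stop("too few genes with positive sampling weight (", sum(w > 0),
         ") to draw ", total, " distinct targets", call. = FALSE)
  pick <- sample(genes, total, prob = w)
  shared <- pick[seq_len(n_shared)]
  own1 <- pick[n_shared + seq_len(n_t - n_shared)]
  own2 <- pick[n_shared + (n_t - n_shared) + seq_len(n_t - n_shared)]
  mk <- function(targets, source) {
    targets <- sort(targets)
    scores <- round(0.5 + stats::runif(length(targets)) / 2, 6)
    names(scores) <- targets
    new_target_table(mirna_id = scenario$mirna_id, source = source,
                     targets = targets, scores = scores)
  }
  list(mk(c(shared, own1), "TargetScan"), mk(c(shared, own2), "miRDB"))
}

new_target_table <- function(mirna_id, source, targets, scores = NULL) {
  structure(list(mirna_id = mirna_id, source = source,
                 targets = targets, scores = scores),
            class = "target_table")
}

#' @export
print.target_table <- function(x, ...) {
  cat("Target table:", x$mirna_id, "from", x$source, "—",
      length(x$targets), "targets\n")
  invisible(x)
}

#' Generate validated-interaction tables
#'
#' Emulates the small exports of three experimental-validation databases
#' by drawing `n_validated_per_db` genes per database from the union of
#' the predicted targets (validated interactions are a sparse subset of
#' what predictors report).
#'
#' @param scenario A [synthetic_scenario()].
#' @param predicted List of the two predictor `target_table`s.
#' @return A list of up to three `target_table` objects.
#' @export
generate_validated_tables <- function(scenario, predicted) {
  stopifnot(inherits(scenario, "mirhost_scenario"))
  set.seed(derive_seed(scenario$seed, 5L))
  pool <- sort(unique(unlist(lapply(predicted, `[[`, "targets"))))
  n <- min(scenario$n_validated_per_db, length(pool))
  lapply(c("miTarBase", "miRNet", "miRWalk"), function(db) {
    new_target_table(mirna_id = scenario$mirna_id, source = db,
                     targets = sort(sample(pool, n)))
  })
}

#' Generate a tissue graph
#'
#' Builds an undirected, weighted Erdős–Rényi-style graph over the full
#' gene universe with expected edge density `edge_density`. Each node
#' carries an attachment propensity of 1, except host-associated target
#' genes (targets that are ground-truth associated in this tissue) whose
#' propensity is `centrality_bias`; the connection probability of a pair
#' is proportional to the product of propensities, rescaled so the
#' expected density over all pairs stays `edge_density` (capped at 1).
#' Edge weights are uniform in `(0, 1]`. No self loops.
#'
#' @param scenario A [synthetic_scenario()].
#' @param tissue One of `scenario$tissues`.
#' @param assoc Optional `tissue_assoc` for this tissue (regenerated if
#'   missing).
#' @param target_union Optional character vector of all predicted targets
#'   (regenerated if missing).
#' @return A `tissue_graph_data` object: `tissue`, `nodes`, `edges`
#'   data.frame (`gene_a`, `gene_b`, `weight`).
#' @export
generate_tissue_graph <- function(scenario, tissue, assoc = NULL,
                                  target_union = NULL) {
  stopifnot(inherits(scenario, "mirhost_scenario"))
  ti <- match(tissue, scenario$tissues)
  if (is.na(ti))
    stop("unknown tissue '", tissue, "'", call. = FALSE)
  if (is.null(assoc)) assoc <- generate_association_vector(scenario, tissue)
  if (is.null(target_union)) {
    pred <- generate_target_predictions(scenario)
    target_union <- unique(unlist(lapply(pred, `[[`, "targets")))
  }
  set.seed(derive_seed(scenario$seed, 3L, ti))
  genes <- scenario$genes
  n <- length(genes)
  hot <- intersect(target_union, assoc$associated)
  a <- rep(1, n)
  a[genes %in% hot] <- scenario$centrality_bias
  if (scenario$edge_density == 0 || n < 2L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
    return(new_tissue_graph_data(tissue, genes, edges))
  }
  # mean pair propensity product, to keep expected density at edge_density
  s1 <- sum(a); s2 <- sum(a^2)
  mean_prod <- (s1^2 - s2) / (n * (n - 1))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- pmin(1, scenario$edge_density * a[idx[, 1L]] * a[idx[, 2L]] / mean_prod)
  keep <- stats::runif(nrow(idx)) < p
  ii <- idx[keep, , drop = FALSE]
  weight <- 1 - stats::runif(nrow(ii))   # in (0, 1]
  edges <- data.frame(gene_a = genes[ii[, 1L]], gene_b = genes[ii[, 2L]],
                      weight = round(weight, 6),
                      stringsAsFactors = FALSE)
  new_tissue_graph_data(tissue, genes, canonical_edges(edges))
}

new_tissue_graph_data <- function(tissue, nodes, edges) {
  structure(list(tissue = tissue, nodes = nodes, edges = edges),
            class = "tissue_graph_data")
}

#' @export
print.tissue_graph_data <- function(x, ...) {
  cat("Tissue graph:", x$tissue, "—", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# store each undirected edge once, endpoints in lexicographic order
canonical_edges <- function(edges) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  out <- data.frame(gene_a = a, gene_b = b, weight = edges$weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic gene-set collection
#'
#' Builds `n_gene_sets` sets with sizes uniform in `gene_set_size_range`,
#' members drawn from the gene universe. When `planted_set_overlap > 0`,
#' the designated set (named `"SET_PLANTED"`) is seeded with that many of
#' the supplied top-ranked target genes (taken in order) before being
#' filled to its drawn size with random non-target genes.
#'
#' @param scenario A [synthetic_scenario()].
#' @param top_targets Character vector of top-ranked target genes; must
#'   contain at least `planted_set_overlap` genes.
#' @return A `gene_set_collection` object (see [read_gmt()]).
#' @export
generate_gene_set_collection <- function(scenario, top_targets = character()) {
  stopifnot(inherits(scenario, "mirhost_scenario"))
  k <- scenario$planted_set_overlap
  if (k > length(top_targets))
    stop("planted_set_overlap (", k, ") exceeds the number of top targets (",
         length(top_targets), ")", call. = FALSE)
  set.seed(derive_seed(scenario$seed, 4L))
  rng <- scenario$gene_set_size_range
  sizes <- sample(seq(rng[1L], rng[2L]), scenario$n_gene_sets, replace = TRUE)
  genes <- scenario$genes
  nm <- c("SET_PLANTED",
          sprintf("SET_%04d", seq_len(scenario$n_gene_sets - 1L)))
  sets <- vector("list", scenario$n_gene_sets)
  planted <- if (k > 0L) top_targets[seq_len(k)] else character()
  for (i in seq_along(sets)) {
    if (i == 1L) {
      size <- max(sizes[i], k)
      fill <- sample(setdiff(genes, top_targets), size - k)
      members <- c(planted, fill)
    } else {
      members <- sample(genes, sizes[i])
    }
    sets[[i]] <- list(name = nm[i],
                      description = paste0("synthetic gene set ", i),
                      members = sort(members))
  }
  new_gene_set_collection(sets)
}

#' Write all inputs of a scenario to disk
#'
#' Materializes every pipeline input for a scenario: per-tissue
#' association tables and edge lists, the two predictor target tables,
#' three validation-database tables, a gene-set collection in GMT format,
#' a ground-truth JSON sidecar, and a ready-to-run analysis configuration
#' (`analysis_config.yaml`). The designated planted gene set is seeded
#' with the scenario's own top-ranked targets in the first tissue
#' (association criterion at the scenario threshold, fractional rank
#' screen at 0.5, top 20).
#'
#' @param scenario A [synthetic_scenario()].
#' @param out_dir Output directory, created if missing.
#' @param min_fr,top_n Fractional-rank screen and truncation used to pick
#'   the planted top targets.
#' @return Invisibly, a list of all written paths.
#' @export
simulate_scenario <- function(scenario, out_dir, min_fr = 0.5, top_n = 20L) {
  stopifnot(inherits(scenario, "mirhost_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assoc <- lapply(scenario$tissues, function(ts)
    generate_association_vector(scenario, ts))
  names(assoc) <- scenario$tissues
  pred <- generate_target_predictions(scenario, assoc[[1L]])
  validated <- generate_validated_tables(scenario, pred)
  target_union <- unique(unlist(lapply(pred, `[[`, "targets")))
  graphs <- lapply(scenario$tissues, function(ts)
    generate_tissue_graph(scenario, ts, assoc[[ts]], target_union))
  names(graphs) <- scenario$tissues

  # top targets in the first tissue anchor the planted gene set
  crit <- association_criterion(scenario$assoc_threshold, "above")
  integrated <- integrate_predicted(pred)
  a1 <- assoc[[1L]]
  assoc_set <- host_associated_genes(a1, crit)
  fr <- fractional_rank(a1$scores[assoc_set])
  filt <- filter_targets(integrated, assoc_set)
  top <- select_top_targets(filt, fr, a1$scores,
                            validated = integrate_validated(validated),
                            min_fr = min_fr, top_n = top_n,
                            host_gene = scenario$host_gene,
                            mirna_id = scenario$mirna_id,
                            tissue = a1$tissue)
  collection <- generate_gene_set_collection(scenario, top$members$gene)

  paths <- list()
  for (ts in scenario$tissues) {
    paths[[paste0("assoc_", ts)]] <-
      write_association_table(assoc[[ts]],
                              file.path(out_dir, paste0("netwas_", ts, ".tsv")))
    paths[[paste0("edges_", ts)]] <-
      write_edge_list(graphs[[ts]],
                      file.path(out_dir, paste0("edges_", ts, ".tsv")))
  }
  paths$targets_targetscan <-
    write_target_table(pred[[1L]], file.path(out_dir, "targets_targetscan.tsv"))
  paths$targets_mirdb <-
    write_target_table(pred[[2L]], file.path(out_dir, "targets_mirdb.tsv"))
  for (i in seq_along(validated)) {
    nmv <- paste0("validated_", tolower(validated[[i]]$source))
    paths[[nmv]] <- write_target_table(
      validated[[i]], file.path(out_dir, paste0(nmv, ".tsv")))
  }
  paths$gene_sets <- write_gmt(collection, file.path(out_dir, "gene_sets.gmt"))

  truth <- list(
    scenario = scenario[setdiff(names(scenario), "genes")],
    associated = lapply(assoc, `[[`, "associated"),
    targets = list(TargetScan = pred[[1L]]$targets,
                   miRDB = pred[[2L]]$targets),
    validated = lapply(stats::setNames(validated,
                                       vapply(validated, `[[`, "", "source")),
                       `[[`, "targets"),
    top_targets_tissue1 = top$members$gene,
    planted_set = "SET_PLANTED"
  )
  paths$ground_truth <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  cfg <- list(
    host_gene = scenario$host_gene,
    mirna_id = scenario$mirna_id,
    tissues = as.list(scenario$tissues),
    association_threshold = scenario$assoc_threshold,
    association_direction = "above",
    min_fr = min_fr,
    top_n = as.integer(top_n),
    min_n = 3L,
    edge_weight_threshold = 0.5,
    overlap_alternative = "depletion",
    centrality_alternative = "greater",
    enrichment_mode = "ora",
    n_perm = 1000L,
    seed = scenario$seed,
    inputs = list(
      predicted = list(
        list(path = "targets_targetscan.tsv", source = "TargetScan"),
        list(path = "targets_mirdb.tsv", source = "miRDB")),
      validated = lapply(validated, function(v)
        list(path = paste0("validated_", tolower(v$source), ".tsv"),
             source = v$source)),
      association = lapply(stats::setNames(scenario$tissues,
                                           scenario$tissues),
                           function(ts) paste0("netwas_", ts, ".tsv")),
      edges = lapply(stats::setNames(scenario$tissues, scenario$tissues),
                     function(ts) paste0("edges_", ts, ".tsv")),
      gene_sets = "gene_sets.gmt"
    )
  )
  paths$analysis_config <- file.path(out_dir, "analysis_config.yaml")
  yaml::write_yaml(cfg, paths$analysis_config)
  invisible(paths)
}
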