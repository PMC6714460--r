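#' Cross-tissue specificity of filtered targets
#'
#' Summarizes in how many tissue networks each filtered target appears:
#' per-target tissue counts, a histogram over counts (a target found in
#' all five tissues contributes 1 to bin "5"), and the pairwise overlap
#' matrix between tissues. The histogram total equals the number of
#' distinct filtered targets across tissues.
#'
#' @param filtered_sets Named list (tissue -> character vector of
#'   filtered target genes).
#' @return A `tissue_specificity` object: `per_target` (named integer),
#'   `histogram` (integer vector over 1..n_tissues), `pairwise` (overlap
#'   count matrix).
#' @export
tissue_specificity_summary <- function(filtered_sets) {
  stopifnot(is.list(filtered_sets), length(filtered_sets) >= 1L,
            !is.null(names(filtered_sets)))
  tissues <- names(filtered_sets)
  all_genes <- sort(unique(unlist(filtered_sets)))
  per_target <- vapply(all_genes, function(g)
    sum(vapply(filtered_sets, function(s) g %in% s, logical(1L))),
    integer(1L))
  histogram <- vapply(seq_along(tissues), function(k)
    sum(per_target == k), integer(1L))
  names(histogram) <- as.character(seq_along(tissues))
  pairwise <- outer(seq_along(tissues), seq_along(tissues),
                    Vectorize(function(i, j)
                      length(intersect(filtered_sets[[i]],
                                       filtered_sets[[j]]))))
  dimnames(pairwise) <- list(tissues, tissues)
  structure(list(per_target = per_target, histogram = histogram,
                 pairwise = pairwise),
            class = "tissue_specificity")
}

#' @export
print.tissue_specificity <- function(x, ...) {
  cat("Tissue specificity of", length(x$per_target), "filtered targets\n")
  cat("  tissues-per-target histogram:",
      paste(names(x$histogram), x$histogram, sep = ":", collapse = "  "),
      "\n")
  invisible(x)
}

#' Load an analysis configuration
#'
#' Reads the YAML configuration produced by [simulate_scenario()] (or
#' written by hand) and resolves all input paths relative to the config
#' file's directory.
#'
#' @param path Path to the YAML file.
#' @return A named list with an added `base_dir` and `config_path`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  required <- c("host_gene", "mirna_id", "tissues",
                "association_threshold", "inputs")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config ", path, " is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  defaults <- list(association_direction = "above", min_fr = 0.5,
                   top_n = 20L, min_n = 3L, edge_weight_threshold = 0.5,
                   overlap_alternative = "depletion",
                   centrality_alternative = "greater",
                   enrichment_mode = "ora", n_perm = 1000L, seed = 1L,
                   host_target_mode = "warn",
                   screen_on = "fractional_rank")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg$base_dir <- dirname(normalizePath(path))
  cfg$config_path <- normalizePath(path)
  cfg
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full host-gene / intronic-miRNA analysis
#'
#' Executes the whole pipeline for one (host gene, miRNA) pair across
#' its tissue panel: read and integrate the predicted target tables
#' (union), pool validated interactions, check host self-targeting,
#' then per tissue — restrict targets to host-associated genes, test the
#' overlap against random expectation, compare fractional ranks of
#' targets vs. all associated genes, compare centrality of
#' host-interacting targets vs. all targets on the tissue graph, select
#' the top-ranked targets and run gene-set enrichment — and finally a
#' cross-tissue specificity summary. All thresholds are stamped into the
#' outputs; with a fixed config and seed the report bundle is
#' byte-identical across runs.
#'
#' @param config Path to a YAML config or a list from
#'   [read_analysis_config()].
#' @param out_dir Output directory for the report bundle.
#' @return Invisibly, a list with the in-memory per-tissue results and
#'   the specificity summary.
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- read_analysis_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rp <- function(p) file.path(config$base_dir, p)
  crit <- association_criterion(config$association_threshold,
                                config$association_direction)

  pred <- with_stage("read_predicted_targets",
    lapply(config$inputs$predicted, function(x)
      read_target_table(rp(x$path), source_label = x$source)))
  integrated <- with_stage("integrate_predicted", integrate_predicted(pred))
  validated_tabs <- with_stage("read_validated_targets",
    lapply(config$inputs$validated %||% list(), function(x)
      read_target_table(rp(x$path), source_label = x$source)))
  validated <- integrate_validated(validated_tabs)
  host_check <- with_stage("host_self_target",
    check_host_self_target(integrated, config$host_gene,
                           mode = config$host_target_mode))
  integrated <- host_check$targets

  collection <- NULL
  if (!is.null(config$inputs$gene_sets))
    collection <- with_stage("read_gene_sets",
                             read_gmt(rp(config$inputs$gene_sets)))

  tissues <- unlist(config$tissues)
  per_tissue <- vector("list", length(tissues))
  names(per_tissue) <- tissues
  filtered_sets <- list()
  stat_rows <- list()

  for (ts in tissues) {
    assoc <- with_stage(paste0("read_association_", ts),
      read_association_table(rp(config$inputs$association[[ts]]),
                             host_gene = config$host_gene, tissue = ts))
    universe <- names(assoc$scores)
    associated <- host_associated_genes(assoc, crit)
    targets_in_universe <- intersect(integrated$targets, universe)
    filtered <- filter_targets(integrated, associated)
    filtered_sets[[ts]] <- filtered

    overlap <- with_stage(paste0("overlap_test_", ts),
      hypergeometric_overlap_test(
        G = length(universe), K = length(associated),
        n = length(targets_in_universe), k = length(filtered),
        alternative = config$overlap_alternative))

    rank_cmp <- if (length(associated)) {
      fr <- fractional_rank(assoc$scores[associated])
      rank_score_comparison(unname(fr[filtered]), unname(fr),
                            min_n = config$min_n)
    } else {
      rank_score_comparison(numeric(), numeric(), min_n = config$min_n)
    }

    graph_data <- with_stage(paste0("read_edges_", ts),
      read_edge_list(rp(config$inputs$edges[[ts]]), tissue = ts,
                     nodes = sort(unique(c(config$host_gene, universe)))))
    graph <- build_graph(graph_data, config$edge_weight_threshold)
    profile <- centrality_profile(graph)
    centrality <- compare_target_centrality(
      profile, all_targets = targets_in_universe,
      interacting_targets = filtered, min_n = config$min_n,
      alternative = config$centrality_alternative)

    top <- if (length(associated)) {
      fr <- fractional_rank(assoc$scores[associated])
      select_top_targets(filtered, fr, assoc$scores, validated = validated,
                         min_fr = config$min_fr, top_n = config$top_n,
                         screen_on = config$screen_on,
                         host_gene = config$host_gene,
                         mirna_id = config$mirna_id, tissue = ts)
    } else NULL

    enr <- NULL
    if (!is.null(collection)) {
      if (identical(config$enrichment_mode, "preranked")) {
        # rank the host-associated genes by fractional rank — the same
        # quantity the filtering stage screens on
        if (length(associated) >= 2L) {
          fr <- fractional_rank(assoc$scores[associated])
          enr <- with_stage(paste0("enrichment_", ts),
            preranked_significance(fr, collection,
                                   n_perm = config$n_perm,
                                   seed = config$seed))
        }
      } else if (!is.null(top) && nrow(top$members) > 0L) {
        enr <- with_stage(paste0("enrichment_", ts),
          overrepresentation_test(top$members$gene, collection,
                                  universe = universe))
      }
    }

    tdir <- file.path(out_dir, ts)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(top))
      write_tsv(top$members, file.path(tdir, "top_targets.tsv"))
    if (!is.null(enr))
      write_tsv(as.data.frame(enr), file.path(tdir, "enrichment.tsv"))

    stat_rows[[ts]] <- data.frame(
      tissue = ts,
      universe_size = overlap$universe_size,
      associated_count = overlap$associated_count,
      target_count = overlap$target_count,
      overlap_count = overlap$overlap,
      expected_overlap = overlap$expected_overlap,
      overlap_alternative = overlap$alternative,
      overlap_p = overlap$p_value,
      rank_test_performed = rank_cmp$performed,
      rank_test_p = rank_cmp$p_value,
      rank_test_stars = if (rank_cmp$performed) rank_cmp$stars
                        else rank_cmp$reason,
      degree_test_performed = centrality$degree$performed,
      degree_test_p = centrality$degree$p_value,
      degree_test_stars = if (centrality$degree$performed)
        centrality$degree$stars else centrality$degree$reason,
      betweenness_test_performed = centrality$betweenness$performed,
      betweenness_test_p = centrality$betweenness$p_value,
      betweenness_test_stars = if (centrality$betweenness$performed)
        centrality$betweenness$stars else centrality$betweenness$reason,
      stringsAsFactors = FALSE)

    per_tissue[[ts]] <- list(overlap = overlap, rank_comparison = rank_cmp,
                             centrality = centrality, top_targets = top,
                             enrichment = enr)
  }

  stats_df <- do.call(rbind, stat_rows)
  rownames(stats_df) <- NULL
  write_tsv(stats_df, file.path(out_dir, "statistics.tsv"))

  spec <- tissue_specificity_summary(filtered_sets)
  write_tsv(data.frame(gene = names(spec$per_target),
                       n_tissues = unname(spec$per_target),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "tissue_specificity_targets.tsv"))
  write_tsv(data.frame(n_tissues = names(spec$histogram),
                       n_targets = unname(spec$histogram),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "tissue_specificity_histogram.tsv"))
  pw <- as.data.frame(spec$pairwise)
  pw <- cbind(tissue = rownames(spec$pairwise), pw)
  write_tsv(pw, file.path(out_dir, "tissue_overlap_matrix.tsv"))

  if (!is.null(config$config_path))
    file.copy(config$config_path, file.path(out_dir, "config.yaml"),
              overwrite = TRUE)
  meta <- list(
    package = "mirhostnet",
    version = as.character(utils::packageVersion("mirhostnet")),
    host_gene = config$host_gene,
    mirna_id = config$mirna_id,
    tissues = tissues,
    association_threshold = config$association_threshold,
    association_direction = config$association_direction,
    min_fr = config$min_fr, top_n = config$top_n, min_n = config$min_n,
    screen_on = config$screen_on,
    edge_weight_threshold = config$edge_weight_threshold,
    overlap_alternative = config$overlap_alternative,
    centrality_alternative = config$centrality_alternative,
    enrichment_mode = config$enrichment_mode,
    n_perm = config$n_perm,
    seed = config$seed,
    host_is_target = host_check$host_is_target,
    config_md5 = if (!is.null(config$config_path))
      unname(tools::md5sum(config$config_path)) else NA_character_)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(per_tissue = per_tissue, specificity = spec,
                 statistics = stats_df, metadata = meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
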