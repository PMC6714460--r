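#' Read a miRNA target table
#'
#' Reads a tab-separated target dump (predicted or validated) with a
#' header. Column names are configurable because real predictor dumps
#' differ in layout. Gene symbols are uppercased on ingest and duplicate
#' (miRNA, gene) rows are dropped; counts are reported via `message()`.
#'
#' @param path File path.
#' @param source_label Label recorded as the table's source; defaults to
#'   the file's `source` column (first value) when present.
#' @param mirna_col,gene_col,score_col Column names in the file;
#'   `score_col` is optional.
#' @return A `target_table` object.
#' @export
read_target_table <- function(path, source_label = NULL,
                              mirna_col = "mirna_id",
                              gene_col = "gene_symbol",
                              score_col = "score") {
  df <- read_tsv_checked(path)
  for (col in c(mirna_col, gene_col))
    if (!col %in% names(df))
      stop("target table ", path, ": missing mandatory column '", col, "'",
           call. = FALSE)
  if (is.null(source_label))
    source_label <- if ("source" %in% names(df)) df$source[1L] else "unknown"
  genes <- toupper(trimws(df[[gene_col]]))
  if (any(!nzchar(genes)))
    stop("target table ", path, ": empty gene symbol", call. = FALSE)
  mirna <- unique(df[[mirna_col]])
  if (length(mirna) != 1L)
    stop("target table ", path, ": expected one miRNA, found ",
         length(mirna), call. = FALSE)
  dup <- duplicated(paste(df[[mirna_col]], genes))
  if (any(dup))
    message("read_target_table: dropped ", sum(dup), " duplicate row(s) of ",
            nrow(df), " in ", basename(path))
  genes_u <- genes[!dup]
  ord <- order(genes_u)
  scores <- NULL
  if (score_col %in% names(df)) {
    scores <- as.numeric(df[[score_col]])[!dup][ord]
    names(scores) <- genes_u[ord]
  }
  new_target_table(mirna_id = mirna, source = source_label,
                   targets = genes_u[ord], scores = scores)
}

#' Write a target table
#' @param table A `target_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(table, path) {
  stopifnot(inherits(table, "target_table"))
  score <- if (is.null(table$scores)) rep(NA_real_, length(table$targets))
           else unname(table$scores[table$targets])
  df <- data.frame(mirna_id = table$mirna_id,
                   gene_symbol = table$targets,
                   source = table$source,
                   score = score, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a host-gene-centric association score table
#'
#' Reads a two-column (gene, score) TSV of tissue-specific functional
#' association scores to one host gene. A row for the host gene itself is
#' dropped with a warning (the self-score is meaningless here). Scores
#' must parse as finite numbers; the offending line number is reported
#' otherwise.
#'
#' @param path File path.
#' @param host_gene Host gene symbol.
#' @param tissue Tissue label stored on the result.
#' @param gene_col,score_col Column names in the file.
#' @return A `tissue_assoc` object (without ground-truth labels).
#' @export
read_association_table <- function(path, host_gene, tissue,
                                   gene_col = "gene_symbol",
                                   score_col = "netwas_score") {
  df <- read_tsv_checked(path)
  for (col in c(gene_col, score_col))
    if (!col %in% names(df))
      stop("association table ", path, ": missing mandatory column '",
           col, "'", call. = FALSE)
  genes <- toupper(trimws(df[[gene_col]]))
  raw <- df[[score_col]]
  scores <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(scores))
  if (length(bad))
    stop("association table ", path, ": non-numeric score '", raw[bad[1L]],
         "' at line ", bad[1L] + 1L, call. = FALSE)
  host_gene <- toupper(host_gene)
  is_host <- genes == host_gene
  if (any(is_host)) {
    warning("association table ", basename(path), ": dropped host gene ",
            host_gene, " self-score row", call. = FALSE)
    genes <- genes[!is_host]
    scores <- scores[!is_host]
  }
  dup <- duplicated(genes)
  if (any(dup)) {
    message("read_association_table: dropped ", sum(dup),
            " duplicate gene row(s) in ", basename(path))
    genes <- genes[!dup]
    scores <- scores[!dup]
  }
  ord <- order(genes)
  scores <- scores[ord]
  names(scores) <- genes[ord]
  new_tissue_assoc(host_gene = host_gene, tissue = tissue, scores = scores)
}

#' Write an association score table
#' @param assoc A `tissue_assoc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(assoc, path) {
  stopifnot(inherits(assoc, "tissue_assoc"))
  df <- data.frame(gene_symbol = names(assoc$scores),
                   netwas_score = unname(assoc$scores),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_symbol), , drop = FALSE]
  write_tsv(df, path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then one gene per field, all
#' tab-separated (the MSigDB convention). Order is preserved;
#' `write_gmt()` followed by `read_gmt()` is the identity on canonical
#' files.
#'
#' @param path File path.
#' @return A `gene_set_collection`: list of `list(name, description,
#'   members)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("GMT file ", path, " is empty", call. = FALSE)
  sets <- vector("list", length(lines))
  seen <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT file ", path, ": line ", i, " has ", length(f),
           " field(s); at least 3 (name, description, gene) required",
           call. = FALSE)
    if (f[1L] %in% seen)
      stop("GMT file ", path, ": duplicate set name '", f[1L], "' at line ",
           i, call. = FALSE)
    seen <- c(seen, f[1L])
    members <- toupper(f[-(1:2)])
    members <- members[nzchar(members)]
    sets[[i]] <- list(name = f[1L], description = f[2L], members = members)
  }
  new_gene_set_collection(sets)
}

new_gene_set_collection <- function(sets) {
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("gene set names must be unique", call. = FALSE)
  if (any(vapply(sets, function(s) length(s$members) == 0L, logical(1L))))
    stop("gene sets must be non-empty", call. = FALSE)
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$members), integer(1L))
  cat("Gene set collection:", length(x), "sets; sizes",
      min(sizes), "-", max(sizes), "\n")
  invisible(x)
}

#' Write a gene-set collection in GMT format
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a tissue graph edge list
#'
#' Reads an undirected weighted edge list (`gene_a`, `gene_b`, `weight`).
#' Edges are stored once with endpoints in lexicographic order regardless
#' of input order. Self loops are format errors; so is the same edge
#' appearing twice with conflicting weights (consistent duplicates are
#' collapsed).
#'
#' @param path File path.
#' @param tissue Tissue label stored on the result.
#' @param nodes Optional character vector of the full node universe
#'   (genes absent from any edge stay as isolated nodes downstream);
#'   defaults to the genes seen in the edges.
#' @return A `tissue_graph_data` object.
#' @export
read_edge_list <- function(path, tissue, nodes = NULL) {
  df <- read_tsv_checked(path)
  for (col in c("gene_a", "gene_b", "weight"))
    if (!col %in% names(df))
      stop("edge list ", path, ": missing mandatory column '", col, "'",
           call. = FALSE)
  a <- toupper(trimws(df$gene_a))
  b <- toupper(trimws(df$gene_b))
  w <- as.numeric(df$weight)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("edge list ", path, ": weights must be finite and > 0",
         call. = FALSE)
  loops <- which(a == b)
  if (length(loops))
    stop("edge list ", path, ": self-loop '", a[loops[1L]], "' at line ",
         loops[1L] + 1L, call. = FALSE)
  edges <- canonical_edges(data.frame(gene_a = a, gene_b = b, weight = w,
                                      stringsAsFactors = FALSE))
  key <- paste(edges$gene_a, edges$gene_b)
  if (anyDuplicated(key)) {
    agg <- tapply(edges$weight, key, function(x) length(unique(x)))
    if (any(agg > 1L)) {
      bad <- names(agg)[agg > 1L][1L]
      stop("edge list ", path, ": duplicate edge '", bad,
           "' with conflicting weights", call. = FALSE)
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  new_tissue_graph_data(tissue, nodes, edges)
}

#' Write a tissue graph edge list
#' @param graph A `tissue_graph_data`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "tissue_graph_data"))
  write_tsv(graph$edges, path)
  invisible(path)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("file ", path, " is empty", call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L)
    stop("file ", path, " has a header but no rows", call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
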