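#' Association criterion
#'
#' The rule deciding which genes count as functionally associated with
#' ("interacting with") the host gene in a tissue network. The literature
#' rarely states a cutoff for network-association scores, so the
#' threshold is explicit, mandatory in pipeline configs, and stamped into
#' every output.
#'
#' @param threshold Numeric score threshold.
#' @param direction `"above"` keeps scores strictly greater than the
#'   threshold, `"below"` strictly smaller.
#' @return An `assoc_criterion` object.
#' @export
association_criterion <- function(threshold, direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  structure(list(threshold = threshold, direction = direction),
            class = "assoc_criterion")
}

#' Genes associated with the host gene in one tissue
#'
#' @param assoc A `tissue_assoc` score vector.
#' @param criterion An [association_criterion()].
#' @return Sorted character vector of genes meeting the criterion; its
#'   length is the fractional-rank denominator `N`.
#' @export
host_associated_genes <- function(assoc, criterion) {
  stopifnot(inherits(assoc, "tissue_assoc"),
            inherits(criterion, "assoc_criterion"))
  if (!length(assoc$scores))
    stop("empty association vector", call. = FALSE)
  keep <- if (criterion$direction == "above")
    assoc$scores > criterion$threshold
  else
    assoc$scores < criterion$threshold
  sort(names(assoc$scores)[keep])
}

#' Restrict integrated targets to host-associated genes
#'
#' The intersection of the predicted-target union with the genes
#' associated with the host gene in one tissue — the per-tissue overlap
#' whose size the overlap test evaluates.
#'
#' @param integrated An `integrated_targets` object or a character vector
#'   of target genes.
#' @param associated Character vector from [host_associated_genes()].
#' @return Sorted character vector of surviving targets.
#' @export
filter_targets <- function(integrated, associated) {
  targets <- if (inherits(integrated, "integrated_targets"))
    integrated$targets else as.character(integrated)
  sort(intersect(targets, associated))
}

#' Fractional ranks of association scores
#'
#' Replaces each score by its rank divided by the number of ranked genes,
#' mapping scores to `(0, 1]`: the highest score gets fractional rank 1.
#' Ties receive the mean of their rank positions, so the mean fractional
#' rank is exactly `(N + 1) / (2 N)`. Fractional ranks are invariant
#' under any strictly increasing transform of the scores, which is what
#' makes them comparable across tissue networks.
#'
#' @param scores Named numeric vector (typically the association scores
#'   restricted to the host-associated genes).
#' @return Named numeric vector of fractional ranks in `(0, 1]`.
#' @export
fractional_rank <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 1L,
            all(is.finite(scores)))
  rank(scores, ties.method = "average") / length(scores)
}

#' Select the top-ranked filtered targets
#'
#' Applies the fractional-rank screen (keep `>= min_fr`, default 0.5,
#' i.e. the top half of the host-associated genes) and truncates to the
#' `top_n` (default 20) highest-ranked targets. Boundary ties are broken
#' by fractional rank descending, then gene symbol ascending, for
#' determinism. Fewer than `top_n` targets may remain; an empty result is
#' legal.
#'
#' @param targets Character vector of filtered targets (within the
#'   host-associated set).
#' @param franks Named fractional ranks over all host-associated genes.
#' @param scores Named raw association scores (for reporting).
#' @param validated Character vector of validated target genes (flags the
#'   report rows).
#' @param min_fr Minimum fractional rank (or raw score, see `screen_on`)
#'   kept.
#' @param top_n Maximum number of targets returned.
#' @param screen_on Whether the `min_fr` screen applies to the
#'   fractional ranks (default) or to the raw scores; ordering is by
#'   fractional rank either way.
#' @param host_gene,mirna_id,tissue Metadata stamped on the result.
#' @return A `filtered_target_set`: metadata plus `members`, a data.frame
#'   (`gene`, `netwas_score`, `fractional_rank`, `validated`) sorted by
#'   fractional rank descending.
#' @export
select_top_targets <- function(targets, franks, scores,
                               validated = character(),
                               min_fr = 0.5, top_n = 20L,
                               screen_on = c("fractional_rank",
                                             "raw_score"),
                               host_gene = NA_character_,
                               mirna_id = NA_character_,
                               tissue = NA_character_) {
  screen_on <- match.arg(screen_on)
  stopifnot(all(targets %in% names(franks)))
  fr <- franks[targets]
  keep <- if (screen_on == "fractional_rank") fr >= min_fr
          else scores[targets] >= min_fr
  genes <- targets[keep]
  fr <- fr[keep]
  ord <- order(-fr, genes)
  genes <- genes[ord][seq_len(min(top_n, length(genes)))]
  members <- data.frame(
    gene = genes,
    netwas_score = if (length(genes)) unname(scores[genes]) else numeric(),
    fractional_rank = if (length(genes)) unname(franks[genes]) else numeric(),
    validated = genes %in% validated,
    stringsAsFactors = FALSE)
  structure(list(host_gene = host_gene, mirna_id = mirna_id,
                 tissue = tissue, n_associated = length(franks),
                 min_fr = min_fr, top_n = as.integer(top_n),
                 members = members),
            class = "filtered_target_set")
}

#' @export
print.filtered_target_set <- function(x, ...) {
  cat("Filtered target set:", x$mirna_id, "->", x$host_gene,
      "in", x$tissue, "—", nrow(x$members), "top targets (fr >=",
      x$min_fr, ", top", x$top_n, "of N =", x$n_associated,
      "associated genes)\n")
  invisible(x)
}
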