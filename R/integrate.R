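#' Integrate predicted target tables by union
#'
#' Prediction algorithms have high false-negative rates, so evidence from
#' multiple predictors is combined by union, not intersection; an
#' intersection mode exists for sensitivity analysis. Per-gene provenance
#' records which sources contributed each target.
#'
#' @param tables List of `target_table` objects for the same miRNA.
#' @param mode `"union"` (default) or `"intersection"`.
#' @return An `integrated_targets` object: `mirna_ids`, `targets` (sorted
#'   character), `provenance` (named list gene -> sources).
#' @export
integrate_predicted <- function(tables, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1L), "target_table")))
  mirnas <- unique(vapply(tables, `[[`, "", "mirna_id"))
  if (length(mirnas) != 1L)
    stop("tables cover different miRNAs (", paste(mirnas, collapse = ", "),
         "); merge mature forms explicitly with merge_mature_forms()",
         call. = FALSE)
  per_source <- lapply(tables, `[[`, "targets")
  targets <- if (mode == "union") Reduce(union, per_source)
             else Reduce(intersect, per_source)
  targets <- sort(unique(targets))
  prov <- lapply(targets, function(g) {
    hit <- vapply(tables, function(t) g %in% t$targets, logical(1L))
    vapply(tables[hit], `[[`, "", "source")
  })
  names(prov) <- targets
  new_integrated_targets(mirna_ids = mirnas, targets = targets,
                         provenance = prov)
}

new_integrated_targets <- function(mirna_ids, targets, provenance) {
  structure(list(mirna_ids = mirna_ids, targets = targets,
                 provenance = provenance),
            class = "integrated_targets")
}

#' @export
print.integrated_targets <- function(x, ...) {
  cat("Integrated targets of", paste(x$mirna_ids, collapse = " + "),
      ":", length(x$targets), "genes\n")
  invisible(x)
}

#' Merge the target sets of two mature forms of one miRNA locus
#'
#' Some loci express two mature miRNAs (e.g. a -3p and a -5p arm); their
#' predicted targets are pooled by union, with provenance entries
#' prefixed by the contributing mature form.
#'
#' @param set_a,set_b `integrated_targets` objects for the two mature
#'   forms.
#' @return An `integrated_targets` object covering both forms.
#' @export
merge_mature_forms <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "integrated_targets"),
            inherits(set_b, "integrated_targets"))
  tag <- function(s) {
    id <- paste(s$mirna_ids, collapse = "+")
    lapply(s$provenance, function(src) paste(id, src, sep = "/"))
  }
  pa <- tag(set_a); pb <- tag(set_b)
  targets <- sort(union(set_a$targets, set_b$targets))
  prov <- lapply(targets, function(g)
    c(if (g %in% names(pa)) pa[[g]], if (g %in% names(pb)) pb[[g]]))
  names(prov) <- targets
  new_integrated_targets(
    mirna_ids = unique(c(set_a$mirna_ids, set_b$mirna_ids)),
    targets = targets, provenance = prov)
}

#' Union of validated miRNA-target interactions
#'
#' Validation databases each hold few interactions, so their exports are
#' pooled. The result only annotates downstream reports (a validated
#' flag); it never gates the analysis.
#'
#' @param tables List (possibly empty) of `target_table` objects.
#' @return Sorted character vector of validated target genes.
#' @export
integrate_validated <- function(tables = list()) {
  if (!length(tables)) return(character())
  stopifnot(all(vapply(tables, inherits, logical(1L), "target_table")))
  sort(unique(unlist(lapply(tables, `[[`, "targets"))))
}

#' Check whether a miRNA is predicted to target its own host gene
#'
#' @param integrated An `integrated_targets` object.
#' @param host_gene Host gene symbol.
#' @param mode `"warn"` keeps the set unchanged with a warning when the
#'   host is present; `"remove"` drops it.
#' @return List with `host_is_target` (logical) and `targets` (the
#'   possibly filtered `integrated_targets`).
#' @export
check_host_self_target <- function(integrated, host_gene,
                                   mode = c("warn", "remove")) {
  mode <- match.arg(mode)
  stopifnot(inherits(integrated, "integrated_targets"))
  host_gene <- toupper(host_gene)
  present <- host_gene %in% integrated$targets
  out <- integrated
  if (present) {
    if (mode == "remove") {
      keep <- setdiff(integrated$targets, host_gene)
      out <- new_integrated_targets(integrated$mirna_ids, keep,
                                    integrated$provenance[keep])
    } else {
      warning("host gene ", host_gene,
              " is among the predicted targets of its own intronic miRNA",
              call. = FALSE)
    }
  }
  list(host_is_target = present, targets = out)
}
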