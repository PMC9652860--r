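#' Build candidate kinase-substrate edges measured in a cohort
#'
#' Joins a kinase-substrate relation catalogue against the molecules actually
#' measured: a relation becomes a candidate edge only if its kinase gene is
#' present in the protein layer AND its substrate site (`GENE_SITE` id) is
#' present in the phosphosite layer. Kinase abundance is always taken from
#' the protein layer. Catalogue order is preserved, so the edge list is
#' deterministic for a given catalogue and cohort.
#'
#' Edge ids use the syntax `"KINASE->GENE_SITE"`, e.g. `"AKT1->GSK3B_S9"`.
#'
#' @param relations data.frame from [read_ks_table()] (columns `kinase`,
#'   `substrate_gene`, `substrate_site`).
#' @param protein,phospho [cohort_matrix()] objects for the two layers.
#' @return data.frame of class `"ks_edges"` with columns `edge_id`,
#'   `kinase_molecule`, `substrate_molecule`.
#' @export
build_edges <- function(relations, protein, phospho) {
  need <- c("kinase", "substrate_gene", "substrate_site")
  if (!is.data.frame(relations) || !all(need %in% names(relations))) {
    eq_abort("FormatError",
             "`relations` must have columns kinase, substrate_gene, substrate_site")
  }
  sub_id <- paste0(relations$substrate_gene, "_", relations$substrate_site)
  keep <- which(relations$kinase %in% molecule_ids(protein) &
                  sub_id %in% molecule_ids(phospho))
  # note: paste0() on zero-length inputs returns length 1, hence the
  # explicit empty branch
  edges <- data.frame(
    edge_id = if (length(keep)) paste0(relations$kinase[keep], "->",
                                       sub_id[keep]) else character(0),
    kinase_molecule = relations$kinase[keep],
    substrate_molecule = sub_id[keep],
    stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges$edge_id), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0L) {
    warning("build_edges: no catalogue relation is measured in this cohort",
            call. = FALSE)
  }
  class(edges) <- c("ks_edges", "data.frame")
  edges
}

#' Restrict edges to a reference edge-id set
#'
#' Keeps only edges whose `edge_id` belongs to `reference_ids` (e.g. the
#' built-in edge-feature list of a deployed model), preserving input order.
#'
#' @param edges `"ks_edges"` data.frame from [build_edges()].
#' @param reference_ids Character vector of edge ids, or a path to a plain
#'   text file with one edge id per line.
#' @return The filtered `"ks_edges"` data.frame.
#' @export
restrict_edges <- function(edges, reference_ids) {
  if (length(reference_ids) == 1L && file.exists(reference_ids)) {
    reference_ids <- readLines(reference_ids, warn = FALSE)
    reference_ids <- reference_ids[nzchar(trimws(reference_ids))]
  }
  if (length(reference_ids) == 0L) {
    eq_abort("ConfigError", "`reference_ids` must be nonempty")
  }
  out <- edges[edges$edge_id %in% reference_ids, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("restrict_edges: no candidate edge matches the reference set",
            call. = FALSE)
  }
  class(out) <- c("ks_edges", "data.frame")
  out
}
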