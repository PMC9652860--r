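#' Run the full edge-biomarker workflow on a cohort
#'
#' Chains the pipeline stages in order: build candidate edges from the
#' relation catalogue, optionally restrict them to a reference edge list
#' and/or to differentially correlated pairs (DCP screen), compute
#' state-stratified edge strengths, optionally pre-filter by response
#' correlation, select edge biomarkers by the repeated-split elastic-net
#' search, refit the final model on all samples at the winning
#' (alpha, lambda) restricted to the selected edges, and evaluate the
#' training-cohort predictions.
#'
#' @param protein,phospho [cohort_matrix()] objects (aligned samples).
#' @param relations Kinase-substrate relation data.frame
#'   (see [read_ks_table()]).
#' @param responses Response table (`sample_id` + drug columns).
#' @param drug Drug to model.
#' @param reference_edges Optional edge-id vector or file for
#'   [restrict_edges()].
#' @param dcp Apply the DCP screen to the candidate edges before the
#'   transformation (logical).
#' @param dcp_min_abs_delta,dcp_alpha_level DCP thresholds
#'   (see [dcp_screen()]).
#' @param selection A [selection_config()].
#' @param out_dir Optional directory; when given, writes `edges.csv`
#'   (edge matrix), `selection.json`, `model.json`, `evaluation.json` and
#'   `run_manifest.json` (the echoed settings).
#' @return List of class `"edgeqnet_run"` with elements `edges`, `stats`,
#'   `edge_matrix`, `dcp` (or `NULL`), `selection`, `model`, `evaluation`.
#' @export
run_pipeline <- function(protein, phospho, relations, responses, drug,
                         reference_edges = NULL, dcp = FALSE,
                         dcp_min_abs_delta = 0.5, dcp_alpha_level = 0.05,
                         selection = selection_config(), out_dir = NULL) {
  edges <- build_edges(relations, protein, phospho)
  if (!is.null(reference_edges)) {
    edges <- restrict_edges(edges, reference_edges)
  }
  dcp_result <- NULL
  if (isTRUE(dcp)) {
    dcp_result <- dcp_screen(protein, phospho, pairs = edges,
                             min_abs_delta = dcp_min_abs_delta,
                             alpha_level = dcp_alpha_level)
    edges <- edges[dcp_result$selected, , drop = FALSE]
    class(edges) <- c("ks_edges", "data.frame")
  }
  if (nrow(edges) == 0L) {
    eq_abort("EmptyFeatureSetError", "no candidate edges survive screening")
  }
  stats <- list(protein = state_stats(protein),
                phosphosite = state_stats(phospho))
  em <- edge_strength(protein, phospho, edges, stats)
  sel <- select_edge_biomarkers(em, responses, drug, selection)
  model <- fit_drug_model(em, responses, drug,
                          alpha = sel$best_alpha, lambda = sel$best_lambda,
                          features = sel$selected_edge_ids,
                          seed = selection$seed)
  pred <- stats::predict(model, em)
  y <- drug_response_vector(em, responses, drug)
  evaluation <- evaluate_predictions(pred, y)
  out <- structure(list(edges = edges, stats = stats, edge_matrix = em,
                        dcp = dcp_result, selection = sel, model = model,
                        evaluation = evaluation),
                   class = "edgeqnet_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_edge_matrix(em, file.path(out_dir, "edges.csv"))
    save_selection(sel, file.path(out_dir, "selection.json"))
    save_model(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(
      list(n = evaluation$n, pearson_r = evaluation$pearson_r,
           r_squared = evaluation$r_squared, p_value = evaluation$p_value,
           r_squared_cod = evaluation$r_squared_cod),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = I(17))
    jsonlite::write_json(
      list(drug = drug, dcp = dcp,
           dcp_min_abs_delta = dcp_min_abs_delta,
           dcp_alpha_level = dcp_alpha_level,
           reference_edges = !is.null(reference_edges),
           selection = unclass(selection)),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = I(17))
  }
  out
}

#' @export
print.edgeqnet_run <- function(x, ...) {
  cat("<edgeqnet_run>\n")
  print(x$selection)
  print(x$model)
  print(x$evaluation)
  invisible(x)
}
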