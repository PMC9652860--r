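#' Cohort expression matrix for one molecular layer
#'
#' Container for a samples x molecules matrix of normalized expression values
#' from one layer (protein abundance or phosphosite intensity), together with
#' the per-sample tumor-state labels used for state-stratified standardization
#' (1 = primary tumor, 2 = metastatic tumor).
#'
#' @param values Numeric matrix, samples in rows, molecules in columns.
#'   Row names are sample ids, column names are molecule ids (protein gene
#'   names, or `GENE_SITE` phosphosite ids such as `"GSK3B_S9"`). All entries
#'   must be finite; molecule ids must be unique.
#' @param states Integer vector of per-sample state labels, values in
#'   `{1, 2}`, one per row of `values` (1 = primary, 2 = metastatic).
#' @param layer `"protein"` or `"phosphosite"`.
#'
#' @return An object of class `"cohort_matrix"`: a list with elements
#'   `values`, `states` (named by sample id) and `layer`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("S", 1:4), c("AKT1", "EGFR", "MTOR")))
#' cohort_matrix(m, states = c(1, 1, 2, 2), layer = "protein")
#' @export
cohort_matrix <- function(values, states, layer = c("protein", "phosphosite")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    eq_abort("FormatError", "`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    eq_abort("FormatError", "`values` must carry sample ids (rownames) and molecule ids (colnames)")
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    eq_abort("DuplicateMoleculeError",
             sprintf("duplicate molecule id '%s' in %s layer", dup, layer),
             molecule = dup)
  }
  if (anyDuplicated(rownames(values))) {
    eq_abort("FormatError", "duplicate sample ids in cohort matrix")
  }
  if (!all(is.finite(values))) {
    eq_abort("FormatError", "cohort matrix contains missing or non-finite values")
  }
  if (length(states) != nrow(values)) {
    eq_abort("FormatError", "length(states) must equal nrow(values)")
  }
  states <- as.integer(states)
  if (anyNA(states) || !all(states %in% c(1L, 2L))) {
    eq_abort("FormatError", "state labels must be 1 (primary) or 2 (metastatic)")
  }
  names(states) <- rownames(values)
  structure(list(values = values, states = states, layer = layer),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %s layer: %d samples x %d molecules (state 1: %d, state 2: %d)\n",
              x$layer, nrow(x$values), ncol(x$values),
              sum(x$states == 1L), sum(x$states == 2L)))
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
molecule_ids <- function(x) colnames(x$values)

# both layers must describe the same samples in the same order
check_aligned <- function(protein, phospho) {
  if (!identical(sample_ids(protein), sample_ids(phospho)) ||
      !identical(unname(protein$states), unname(phospho$states))) {
    eq_abort("FormatError",
             "protein and phosphosite cohort matrices must share sample ids, order and states")
  }
  invisible(TRUE)
}

#' Single-patient expression profile
#'
#' @param protein Named numeric vector of protein expression (names = gene).
#' @param phosphosite Named numeric vector of phosphosite expression
#'   (names = `GENE_SITE` ids).
#' @param sample_id Sample identifier.
#' @param state Tumor state, 1 (primary) or 2 (metastatic).
#' @return Object of class `"patient_profile"`.
#' @export
patient_profile <- function(protein, phosphosite, sample_id = "patient", state = 1L) {
  validate_layer <- function(v, layer) {
    if (is.null(names(v)) || any(names(v) == "")) {
      eq_abort("FormatError", sprintf("%s values must be named by molecule id", layer))
    }
    if (anyDuplicated(names(v))) {
      dup <- names(v)[duplicated(names(v))][1]
      eq_abort("DuplicateMoleculeError",
               sprintf("duplicate molecule id '%s' in %s layer", dup, layer),
               molecule = dup)
    }
    if (!all(is.finite(v))) {
      eq_abort("FormatError", sprintf("missing or non-finite value in %s layer", layer))
    }
    v
  }
  state <- as.integer(state)
  if (length(state) != 1L || is.na(state) || !state %in% c(1L, 2L)) {
    eq_abort("FormatError", "state must be 1 (primary) or 2 (metastatic)")
  }
  structure(list(protein = validate_layer(protein, "protein"),
                 phosphosite = validate_layer(phosphosite, "phosphosite"),
                 sample_id = sample_id, state = state),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> '%s' (state %d): %d proteins, %d phosphosites\n",
              x$sample_id, x$state, length(x$protein), length(x$phosphosite)))
  invisible(x)
}
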