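# Readers/writers for every external table the pipeline touches.
# All tables are plain text: 2-column CSV per patient layer, a cohort
# manifest CSV, a kinase-substrate TSV mirroring the public
# Kinase_Substrate_Dataset column names, and versioned JSON for models.

MODEL_SCHEMA_VERSION <- 1L

# -- two-column expression CSV ----------------------------------------------

# Parses one layer file. Header is optional and auto-detected: if the second
# field of the first row does not parse as a number, the row is a header.
# Errors carry the offending file row number (header included in the count).
parse_expression_csv <- function(path, layer) {
  if (!file.exists(path)) {
    eq_abort("FormatError", sprintf("file not found: %s", path), path = path)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    eq_abort("FormatError", sprintf("empty expression file: %s", path), path = path)
  }
  rows <- which(keep)
  fields <- strsplit(lines[rows], ",", fixed = TRUE)
  # strsplit drops a trailing empty field ("GENE," -> 1 field); restore it
  fields <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) == 1L && endsWith(trimws(lines[rows[i]]), ",")) c(f, "") else f
  })
  start <- 1L
  second <- if (length(fields[[1]]) >= 2L) trimws(fields[[1]][2]) else ""
  # header iff the first row's second field is non-numeric text; an EMPTY
  # second field is a missing value, not a header
  if (nzchar(second) && is.na(suppressWarnings(as.numeric(second)))) start <- 2L
  if (start > length(fields)) {
    eq_abort("FormatError", sprintf("no data rows in %s", path), path = path)
  }
  ids <- character(0)
  vals <- numeric(0)
  for (i in start:length(fields)) {
    f <- trimws(fields[[i]])
    row <- rows[i]
    if (length(f) != 2L) {
      eq_abort("FormatError",
               sprintf("%s row %d: expected 2 comma-separated columns, got %d",
                       path, row, length(f)), path = path, row = row)
    }
    if (f[1] == "") {
      eq_abort("FormatError", sprintf("%s row %d: empty molecule id", path, row),
               path = path, row = row)
    }
    v <- suppressWarnings(as.numeric(f[2]))
    if (is.na(v) || !is.finite(v)) {
      eq_abort("FormatError",
               sprintf("%s row %d: missing or non-numeric expression value ('%s')",
                       path, row, f[2]), path = path, row = row)
    }
    ids <- c(ids, f[1])
    vals <- c(vals, v)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    eq_abort("DuplicateMoleculeError",
             sprintf("duplicate molecule id '%s' in %s (%s layer)", dup, path, layer),
             molecule = dup, path = path)
  }
  names(vals) <- ids
  vals
}

#' Read a single patient's protein + phosphosite CSV pair
#'
#' Each file has two columns: molecule id (protein gene name, or `GENE_SITE`
#' phosphosite id) and normalized expression value. A header row is optional
#' and auto-detected. Duplicate ids and missing values are rejected.
#'
#' @param path_protein Path to the protein expression CSV.
#' @param path_phospho Path to the phosphosite expression CSV.
#' @param state Tumor state of the sample: 1 (primary) or 2 (metastatic).
#' @param sample_id Optional sample identifier (defaults to the protein
#'   file name without extension).
#' @return A [patient_profile()].
#' @export
read_patient_csv <- function(path_protein, path_phospho, state,
                             sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path_protein))
  }
  patient_profile(protein = parse_expression_csv(path_protein, "protein"),
                  phosphosite = parse_expression_csv(path_phospho, "phosphosite"),
                  sample_id = sample_id, state = state)
}

# -- cohort manifest ---------------------------------------------------------

#' Read a full cohort from a manifest
#'
#' The manifest is a CSV with columns `sample_id`, `state`, `protein_file`,
#' `phospho_file`, followed by one numeric column per drug holding observed
#' TCGI (percent tumor cell growth inhibition). File paths are resolved
#' relative to the manifest's directory. Cohort matrices are restricted to
#' the molecules measured in every sample (intersection); dropped molecule
#' ids are reported in a message and attached as the `dropped` element.
#'
#' @param manifest Path to the manifest CSV.
#' @param quiet Suppress the dropped-molecule message.
#' @return List with elements `protein` and `phosphosite`
#'   ([cohort_matrix()] objects), `responses` (data.frame: `sample_id` plus
#'   one column per drug) and `dropped` (list of dropped molecule ids per
#'   layer).
#' @export
read_cohort <- function(manifest, quiet = FALSE) {
  if (!file.exists(manifest)) {
    eq_abort("MissingSampleError", sprintf("manifest not found: %s", manifest))
  }
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "state", "protein_file", "phospho_file")
  missing_col <- setdiff(required, names(man))
  if (length(missing_col)) {
    eq_abort("FormatError",
             sprintf("manifest lacks required column(s): %s",
                     paste(missing_col, collapse = ", ")))
  }
  if (nrow(man) == 0L) {
    eq_abort("MissingSampleError", "manifest lists no samples")
  }
  if (anyDuplicated(man$sample_id)) {
    eq_abort("FormatError", "duplicate sample_id in manifest")
  }
  if (!all(man$state %in% c(1, 2))) {
    bad <- man$state[!man$state %in% c(1, 2)][1]
    eq_abort("FormatError",
             sprintf("state must be 1 (primary) or 2 (metastatic); got '%s'", bad))
  }
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  profiles <- lapply(seq_len(nrow(man)), function(i) {
    pf <- resolve(man$protein_file[i])
    sf <- resolve(man$phospho_file[i])
    if (!file.exists(pf) || !file.exists(sf)) {
      eq_abort("MissingSampleError",
               sprintf("files for sample '%s' not found (%s)", man$sample_id[i],
                       paste(c(pf, sf)[!file.exists(c(pf, sf))], collapse = ", ")),
               sample_id = man$sample_id[i])
    }
    read_patient_csv(pf, sf, state = man$state[i], sample_id = man$sample_id[i])
  })
  build_layer <- function(layer) {
    per_sample <- lapply(profiles, `[[`, layer)
    common <- Reduce(intersect, lapply(per_sample, names))
    all_ids <- unique(unlist(lapply(per_sample, names)))
    dropped <- setdiff(all_ids, common)
    if (length(common) == 0L) {
      eq_abort("FormatError",
               sprintf("no %s molecules shared by all samples", layer))
    }
    values <- do.call(rbind, lapply(per_sample, function(v) v[common]))
    dimnames(values) <- list(man$sample_id, common)
    list(matrix = cohort_matrix(values, states = man$state, layer = layer),
         dropped = dropped)
  }
  prot <- build_layer("protein")
  phos <- build_layer("phosphosite")
  dropped <- list(protein = prot$dropped, phosphosite = phos$dropped)
  n_drop <- length(dropped$protein) + length(dropped$phosphosite)
  if (n_drop > 0 && !quiet) {
    message(sprintf(
      "read_cohort: dropped %d molecule(s) not measured in every sample (%s)",
      n_drop, paste(utils::head(unlist(dropped), 10), collapse = ", ")))
  }
  drug_cols <- setdiff(names(man), required)
  responses <- man[, c("sample_id", drug_cols), drop = FALSE]
  for (d in drug_cols) {
    responses[[d]] <- suppressWarnings(as.numeric(responses[[d]]))
    if (anyNA(responses[[d]])) {
      eq_abort("FormatError", sprintf("non-numeric TCGI value for drug '%s'", d))
    }
  }
  list(protein = prot$matrix, phosphosite = phos$matrix,
       responses = responses, dropped = dropped)
}

# -- kinase-substrate relation table ----------------------------------------

#' Read a kinase-substrate relation table
#'
#' Tab-separated table with header columns `KINASE`, `SUB_GENE` and
#' `SUB_MOD_RSD` (residue + position, e.g. `"S473"`); extra columns are
#' ignored. The format mirrors public kinase-substrate catalogues so an
#' exported PhosphoSitePlus/NetworKIN-style table can be used directly.
#' Duplicate (kinase, substrate gene, site) triples are removed, keeping the
#' first occurrence.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `kinase`, `substrate_gene`,
#'   `substrate_site`, `source`.
#' @export
read_ks_table <- function(path) {
  if (!file.exists(path)) {
    eq_abort("FormatError", sprintf("file not found: %s", path), path = path)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("KINASE", "SUB_GENE", "SUB_MOD_RSD")) {
    if (!col %in% names(tab)) {
      eq_abort("FormatError", sprintf("kinase-substrate table lacks column '%s'", col),
               column = col)
    }
  }
  rel <- data.frame(kinase = as.character(tab$KINASE),
                    substrate_gene = as.character(tab$SUB_GENE),
                    substrate_site = as.character(tab$SUB_MOD_RSD),
                    source = if ("SOURCE" %in% names(tab))
                      as.character(tab$SOURCE) else basename(path),
                    stringsAsFactors = FALSE)
  if (any(rel$kinase == "" | rel$substrate_site == "")) {
    eq_abort("FormatError", "kinase-substrate table has empty KINASE or SUB_MOD_RSD value")
  }
  rel[!duplicated(rel[c("kinase", "substrate_gene", "substrate_site")]), ,
      drop = FALSE]
}

# -- edge matrix CSV ---------------------------------------------------------

#' Write / read an edge-strength matrix as CSV
#'
#' Rows are samples; the first two columns are `sample_id` and `state`,
#' followed by one column per edge id.
#'
#' @param em An `edge_matrix` (see [edge_strength()]).
#' @param path Output CSV path.
#' @return `write_edge_matrix()` returns `path` invisibly;
#'   `read_edge_matrix()` returns an `edge_matrix`.
#' @export
write_edge_matrix <- function(em, path) {
  df <- data.frame(sample_id = rownames(em$values), state = em$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(em$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_edge_matrix
#' @export
read_edge_matrix <- function(path) {
  if (!file.exists(path)) {
    eq_abort("FormatError", sprintf("file not found: %s", path), path = path)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "state") %in% names(df))) {
    eq_abort("FormatError", "edge matrix CSV lacks sample_id/state columns")
  }
  ids <- df$sample_id
  states <- as.integer(df$state)
  vals <- as.matrix(df[, setdiff(names(df), c("sample_id", "state")), drop = FALSE])
  if (!is.numeric(vals) || !all(is.finite(vals))) {
    eq_abort("FormatError", "edge matrix CSV contains non-numeric entries")
  }
  rownames(vals) <- ids
  edge_matrix(vals, states)
}

# -- model persistence -------------------------------------------------------

#' Save / load a fitted drug model as versioned JSON
#'
#' The JSON document stores the drug name, penalty hyperparameters, the
#' intercept and coefficients on the original edge-strength scale, the
#' ordered feature (edge) ids and the training metadata (including feature
#' scaling constants), under a `schema_version` field. Numbers are written
#' at full double precision so a save/load round trip reproduces
#' predictions bit-for-bit.
#'
#' @param model A fitted [fit_drug_model()] object.
#' @param path Output JSON path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `drug_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "drug_model")) {
    eq_abort("ConfigError", "`model` must be a fitted drug_model")
  }
  doc <- list(schema_version = MODEL_SCHEMA_VERSION,
              drug = model$drug,
              alpha = model$alpha,
              lambda = model$lambda,
              intercept = model$intercept,
              features = as.list(model$features),
              coefficients = as.list(unname(model$coefficients)),
              training_meta = model$training_meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    eq_abort("ModelIOError", sprintf("model file not found: %s", path))
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    eq_abort("ModelIOError",
                             sprintf("cannot parse model file %s: %s", path,
                                     conditionMessage(e)))
                  })
  need <- c("schema_version", "drug", "alpha", "lambda", "intercept",
            "features", "coefficients", "training_meta")
  if (!is.list(doc) || !all(need %in% names(doc))) {
    eq_abort("ModelIOError",
             sprintf("model file %s is missing required fields", path))
  }
  if (!identical(as.integer(doc$schema_version), MODEL_SCHEMA_VERSION)) {
    eq_abort("ModelIOError",
             sprintf("unsupported model schema version '%s' (expected %d)",
                     doc$schema_version, MODEL_SCHEMA_VERSION))
  }
  features <- as.character(unlist(doc$features))
  coefs <- as.numeric(unlist(doc$coefficients))
  if (length(features) != length(coefs)) {
    eq_abort("ModelIOError", "model file features/coefficients length mismatch")
  }
  names(coefs) <- features
  meta <- doc$training_meta
  for (f in c("center", "scale")) {
    if (!is.null(meta[[f]])) meta[[f]] <- as.numeric(unlist(meta[[f]]))
  }
  new_drug_model(drug = doc$drug, alpha = doc$alpha, lambda = doc$lambda,
                 intercept = doc$intercept, coefficients = coefs,
                 training_meta = meta)
}
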