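# Synthetic cohort generator with planted kinase-substrate signal.
#
# Emulates the study setting the pipeline targets: a small two-state tumor
# cohort (primary / metastatic) with protein and phosphosite layers, a
# kinase-substrate relation catalogue, and an observed per-drug TCGI that is
# linear in the TRUE edge strengths of a few informative kinase-substrate
# pairs. Kinase columns are standard normal within each state; an
# informative substrate site is rho * kinase + sqrt(1 - rho^2) * sd_e * eps,
# so at the default sd_e = 1 its true within-state correlation with the
# kinase is exactly rho. Decoy sites are independent noise. The true edge
# strength of an informative pair is its state-stratified z-score product
# computed with the cohort's own within-state mean/SD — the pipeline's
# feature definition — so the response lies exactly in the model class the
# pipeline fits and the noiseless optimum is achievable:
#   TCGI = intercept + sum_e c_e * strength_e + N(0, noise_sd_response).

#' Synthetic-cohort configuration
#'
#' @param n_samples Cohort size (default 31, split 16 primary / 15
#'   metastatic; both states need >= 4 samples).
#' @param n_kinases Number of protein-layer kinases.
#' @param n_substrates Number of phosphosite-layer substrate sites (one site
#'   per substrate gene).
#' @param n_relations Catalogue size; the first `n_relations` substrates are
#'   each assigned a random kinase (must be `<= n_substrates`).
#' @param n_informative_edges Number of relations that carry response signal.
#' @param true_coefficients Signal coefficients, length
#'   `n_informative_edges` (default `c(3, -2, 1.5)`).
#' @param edge_correlation Within-state kinase-substrate correlation of
#'   informative pairs, in (0, 1).
#' @param noise_sd_expression SD of idiosyncratic expression noise (decoy
#'   sites, and the orthogonal component of informative sites).
#' @param noise_sd_response SD of the Gaussian noise added to TCGI.
#' @param tcgi_intercept Baseline TCGI (percent scale).
#' @param drug Drug name used in the response table.
#' @param seed Integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(n_samples = 31L, n_kinases = 20L,
                         n_substrates = 53L, n_relations = 53L,
                         n_informative_edges = 3L,
                         true_coefficients = c(3, -2, 1.5),
                         edge_correlation = 0.9,
                         noise_sd_expression = 1,
                         noise_sd_response = 0.1,
                         tcgi_intercept = 50, drug = "drug1", seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", lower = 8L)
  n_kinases <- check_count(n_kinases, "n_kinases")
  n_substrates <- check_count(n_substrates, "n_substrates")
  n_relations <- check_count(n_relations, "n_relations")
  n_informative_edges <- check_count(n_informative_edges,
                                     "n_informative_edges", lower = 0L)
  if (n_relations > n_substrates) {
    eq_abort("ConfigError", "n_relations must be <= n_substrates")
  }
  if (n_informative_edges > n_relations) {
    eq_abort("ConfigError", "n_informative_edges must be <= n_relations")
  }
  if (length(true_coefficients) != n_informative_edges ||
      any(!is.finite(true_coefficients))) {
    eq_abort("ConfigError",
             "length(true_coefficients) must equal n_informative_edges")
  }
  check_number(edge_correlation, "edge_correlation", lower = 1e-9,
               upper = 1 - 1e-9)
  check_number(noise_sd_expression, "noise_sd_expression", lower = 0)
  check_number(noise_sd_response, "noise_sd_response", lower = 0)
  check_number(tcgi_intercept, "tcgi_intercept")
  seed <- check_count(seed, "seed", lower = 0L)
  n1 <- ceiling(n_samples / 2)
  if (n1 < 4L || n_samples - n1 < 4L) {
    eq_abort("ConfigError", "each state needs >= 4 samples")
  }
  structure(list(n_samples = n_samples, n_kinases = n_kinases,
                 n_substrates = n_substrates, n_relations = n_relations,
                 n_informative_edges = n_informative_edges,
                 true_coefficients = true_coefficients,
                 edge_correlation = edge_correlation,
                 noise_sd_expression = noise_sd_expression,
                 noise_sd_response = noise_sd_response,
                 tcgi_intercept = tcgi_intercept, drug = drug, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic cohort with planted edge signal
#'
#' @param config A [synth_config()].
#' @return List with `protein` and `phosphosite` ([cohort_matrix()]),
#'   `relations` (kinase-substrate data.frame as from [read_ks_table()]),
#'   `responses` (data.frame: `sample_id` + one drug column of observed
#'   TCGI), and `truth` (list: `informative_edge_ids`,
#'   `true_coefficients` named by edge id, `true_tcgi` — the noise-free
#'   response — and the `config`).
#' @export
generate_cohort <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) {
    eq_abort("ConfigError", "`config` must come from synth_config()")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_samples
  n1 <- ceiling(n / 2)
  states <- rep(c(1L, 2L), c(n1, n - n1))
  ids <- sprintf("S%03d", seq_len(n))
  kin_ids <- sprintf("KIN%03d", seq_len(config$n_kinases))
  sub_genes <- sprintf("SUB%03d", seq_len(config$n_substrates))
  residues <- sample(c("S", "T", "Y"), config$n_substrates, replace = TRUE)
  positions <- sample(1:999, config$n_substrates, replace = TRUE)
  sites <- paste0(residues, positions)
  sub_ids <- paste0(sub_genes, "_", sites)

  prot <- matrix(stats::rnorm(n * config$n_kinases), n, config$n_kinases,
                 dimnames = list(ids, kin_ids))

  rel_kinase <- sample(kin_ids, config$n_relations, replace = TRUE)
  informative_idx <- if (config$n_informative_edges > 0)
    sort(sample(config$n_relations, config$n_informative_edges)) else integer(0)
  # informative edges get distinct kinases: two planted substrates driven by
  # the same kinase would make their edge features ~0.9-correlated and exact
  # support recovery ill-posed; decoy edges may still share these kinases
  # (their features stay uncorrelated with the planted ones)
  if (length(informative_idx) > 0) {
    if (config$n_informative_edges > config$n_kinases) {
      eq_abort("ConfigError", "n_informative_edges must be <= n_kinases")
    }
    rel_kinase[informative_idx] <- sample(kin_ids, config$n_informative_edges)
  }

  rho <- config$edge_correlation
  sd_e <- config$noise_sd_expression
  phos <- matrix(stats::rnorm(n * config$n_substrates, sd = sd_e),
                 n, config$n_substrates, dimnames = list(ids, sub_ids))
  for (i in informative_idx) {
    phos[, i] <- rho * prot[, rel_kinase[i]] +
      sqrt(1 - rho^2) * sd_e * stats::rnorm(n)
  }

  relations <- data.frame(kinase = rel_kinase,
                          substrate_gene = sub_genes[seq_len(config$n_relations)],
                          substrate_site = sites[seq_len(config$n_relations)],
                          source = "synthetic", stringsAsFactors = FALSE)
  informative_edge_ids <- if (length(informative_idx))
    paste0(rel_kinase[informative_idx], "->", sub_ids[informative_idx])
  else character(0)
  true_coefficients <- config$true_coefficients
  names(true_coefficients) <- informative_edge_ids

  # within-state z-score of a column, sample SD (the pipeline's standardization)
  zcol <- function(x) {
    z <- x
    for (k in c(1L, 2L)) {
      rows <- states == k
      z[rows] <- (x[rows] - mean(x[rows])) / stats::sd(x[rows])
    }
    z
  }
  true_tcgi <- rep(config$tcgi_intercept, n)
  for (j in seq_along(informative_idx)) {
    i <- informative_idx[j]
    true_tcgi <- true_tcgi +
      true_coefficients[j] * zcol(prot[, rel_kinase[i]]) * zcol(phos[, i])
  }
  tcgi <- true_tcgi + stats::rnorm(n, sd = config$noise_sd_response)
  names(true_tcgi) <- ids

  responses <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  responses[[config$drug]] <- tcgi

  list(protein = cohort_matrix(prot, states, "protein"),
       phosphosite = cohort_matrix(phos, states, "phosphosite"),
       relations = relations,
       responses = responses,
       truth = list(informative_edge_ids = informative_edge_ids,
                    true_coefficients = true_coefficients,
                    true_tcgi = true_tcgi,
                    config = config))
}

#' Generate held-out samples for a synthetic cohort
#'
#' Draws new samples from the same generative model as `cohort` (same
#' relations, informative pairs and coefficients). Their true TCGI is
#' defined through edge strengths standardized against the REFERENCE
#' cohort's state statistics — mirroring how a deployed model transforms a
#' new patient with frozen reference statistics — plus the configured
#' response noise.
#'
#' @param cohort Output of [generate_cohort()].
#' @param n_samples Number of held-out samples (split between the states).
#' @param seed RNG seed for the new draw.
#' @return List with `protein`, `phosphosite` ([cohort_matrix()]),
#'   `responses` (data.frame) and `truth` (noise-free TCGI vector).
#' @export
generate_holdout <- function(cohort, n_samples = 31L, seed = 1L) {
  config <- cohort$truth$config
  n <- check_count(n_samples, "n_samples", lower = 8L)
  seed <- check_count(seed, "seed", lower = 0L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  n1 <- ceiling(n / 2)
  states <- rep(c(1L, 2L), c(n1, n - n1))
  ids <- sprintf("H%03d", seq_len(n))
  kin_ids <- colnames(cohort$protein$values)
  sub_ids <- colnames(cohort$phosphosite$values)
  prot <- matrix(stats::rnorm(n * length(kin_ids)), n, length(kin_ids),
                 dimnames = list(ids, kin_ids))
  sd_e <- config$noise_sd_expression
  phos <- matrix(stats::rnorm(n * length(sub_ids), sd = sd_e),
                 n, length(sub_ids), dimnames = list(ids, sub_ids))
  rho <- config$edge_correlation
  info <- cohort$truth$informative_edge_ids
  kin_of <- sub("->.*$", "", info)
  sub_of <- sub("^.*->", "", info)
  for (j in seq_along(info)) {
    phos[, sub_of[j]] <- rho * prot[, kin_of[j]] +
      sqrt(1 - rho^2) * sd_e * stats::rnorm(n)
  }
  ref <- list(protein = state_stats(cohort$protein),
              phosphosite = state_stats(cohort$phosphosite))
  zref <- function(vals, stats_, id) {
    k <- as.character(states)
    (vals - stats_$mean[id, k]) / stats_$sd[id, k]
  }
  true_tcgi <- rep(config$tcgi_intercept, n)
  for (j in seq_along(info)) {
    true_tcgi <- true_tcgi +
      cohort$truth$true_coefficients[j] *
        zref(prot[, kin_of[j]], ref$protein, kin_of[j]) *
        zref(phos[, sub_of[j]], ref$phosphosite, sub_of[j])
  }
  names(true_tcgi) <- ids
  responses <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  responses[[config$drug]] <- true_tcgi +
    stats::rnorm(n, sd = config$noise_sd_response)
  list(protein = cohort_matrix(prot, states, "protein"),
       phosphosite = cohort_matrix(phos, states, "phosphosite"),
       responses = responses, truth = true_tcgi)
}

#' Write a generated cohort to a plain-text fixture tree
#'
#' Produces exactly the files [read_cohort()] and [read_ks_table()] consume:
#' per-sample protein/phosphosite CSV pairs, `manifest.csv`,
#' `ks_table.tsv`, and `truth.json` recording the planted signal.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_fixtures <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sample_ids(cohort$protein)
  protein_file <- paste0(ids, "_protein.csv")
  phospho_file <- paste0(ids, "_phospho.csv")
  for (i in seq_along(ids)) {
    write_two_col <- function(v, path) {
      writeLines(paste(names(v), format(v, digits = 17, scientific = FALSE,
                                        trim = TRUE), sep = ","),
                 file.path(dir, path))
    }
    write_two_col(cohort$protein$values[i, ], protein_file[i])
    write_two_col(cohort$phosphosite$values[i, ], phospho_file[i])
  }
  man <- data.frame(sample_id = ids,
                    state = unname(cohort$protein$states),
                    protein_file = protein_file,
                    phospho_file = phospho_file,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (d in setdiff(names(cohort$responses), "sample_id")) {
    man[[d]] <- cohort$responses[[d]][match(ids, cohort$responses$sample_id)]
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  ks <- data.frame(KINASE = cohort$relations$kinase,
                   SUB_GENE = cohort$relations$substrate_gene,
                   SUB_MOD_RSD = cohort$relations$substrate_site,
                   SOURCE = cohort$relations$source)
  utils::write.table(ks, file.path(dir, "ks_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(informative_edge_ids = as.list(cohort$truth$informative_edge_ids),
         true_coefficients = as.list(unname(cohort$truth$true_coefficients)),
         true_tcgi = as.list(unname(cohort$truth$true_tcgi)),
         config = unclass(cohort$truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' Score selection against the planted truth
#'
#' @param selection An `"edge_selection"` from [select_edge_biomarkers()].
#' @param truth The `truth` element of [generate_cohort()] output.
#' @return List with `sensitivity` (recovered fraction of informative
#'   edges), `specificity` (rejected fraction of decoys) and
#'   `sign_agreement` (fraction of recovered informative edges whose fitted
#'   coefficient sign matches the planted sign; `NaN` when none recovered).
#' @export
score_recovery <- function(selection, truth) {
  stopifnot(inherits(selection, "edge_selection"))
  informative <- truth$informative_edge_ids
  universe <- selection$candidate_edge_ids
  if (!all(informative %in% universe)) {
    eq_abort("ConfigError",
             "selection and truth refer to different edge universes")
  }
  decoys <- setdiff(universe, informative)
  selected <- selection$selected_edge_ids
  recovered <- intersect(selected, informative)
  sens <- if (length(informative)) length(recovered) / length(informative) else NaN
  specificity <- if (length(decoys))
    sum(!decoys %in% selected) / length(decoys) else NaN
  sign_ok <- mean(sign(selection$coefficients[recovered]) ==
                    sign(truth$true_coefficients[recovered]))
  list(sensitivity = sens, specificity = specificity, sign_agreement = sign_ok)
}
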