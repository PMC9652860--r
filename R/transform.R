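# Edge transformation: state-stratified z-score products.
#
# For sample j in state k, the strength of edge <u-v> is
#   ((x_ujk - mu_uk) / sigma_uk) * ((x_vjk - mu_vk) / sigma_vk)
# where mu/sigma are the within-state mean and sample standard deviation
# (ddof = 1) of kinase u (protein layer) and substrate site v (phosphosite
# layer). Summed over the samples of one state, the strengths of an edge
# equal (n_k - 1) times the within-state Pearson correlation of the two
# molecule columns — the identity used as a correctness oracle in the tests.

#' Per-state mean/SD statistics for a cohort layer
#'
#' @param matrix A [cohort_matrix()].
#' @return Object of class `"state_stats"`: list with `mean` and `sd`
#'   (molecules x states matrices, columns named by state label), `n`
#'   (samples per state), `constant` (ids of molecules with zero SD in some
#'   state, flagged with a warning) and `layer`.
#' @export
state_stats <- function(matrix) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  states <- sort(unique(matrix$states))
  n_k <- vapply(states, function(k) sum(matrix$states == k), integer(1))
  names(n_k) <- as.character(states)
  low <- n_k < 2L
  if (any(low)) {
    eq_abort("DegenerateStateError",
             sprintf("state %s has %d sample(s); >= 2 required for SD",
                     names(n_k)[low][1], n_k[low][1]),
             state = as.integer(names(n_k)[low][1]))
  }
  p <- ncol(matrix$values)
  mu <- sigma <- base::matrix(NA_real_, p, length(states),
                              dimnames = list(colnames(matrix$values),
                                              as.character(states)))
  for (k in states) {
    sub <- matrix$values[matrix$states == k, , drop = FALSE]
    m <- colMeans(sub)
    mu[, as.character(k)] <- m
    sigma[, as.character(k)] <-
      sqrt(colSums(sweep(sub, 2L, m)^2) / (nrow(sub) - 1))
  }
  constant <- rownames(sigma)[apply(sigma == 0, 1L, any)]
  if (length(constant)) {
    warning(sprintf("state_stats: %d molecule(s) constant within a state (%s)",
                    length(constant),
                    paste(utils::head(constant, 5), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(mean = mu, sd = sigma, n = n_k, constant = constant,
                 layer = matrix$layer),
            class = "state_stats")
}

#' @export
print.state_stats <- function(x, ...) {
  cat(sprintf("<state_stats> %s layer: %d molecules, states {%s}, n = {%s}\n",
              x$layer, nrow(x$mean), paste(colnames(x$mean), collapse = ", "),
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Edge-strength matrix container
#'
#' @param values Numeric samples x edges matrix (dimnames required).
#' @param states Per-sample state labels (1/2).
#' @return Object of class `"edge_matrix"`.
#' @export
edge_matrix <- function(values, states) {
  if (!is.matrix(values) || !is.numeric(values) || !all(is.finite(values))) {
    eq_abort("FormatError", "edge matrix must be a finite numeric matrix")
  }
  states <- as.integer(states)
  if (length(states) != nrow(values) || !all(states %in% c(1L, 2L))) {
    eq_abort("FormatError", "edge matrix states must be 1/2, one per sample")
  }
  names(states) <- rownames(values)
  structure(list(values = values, states = states), class = "edge_matrix")
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat(sprintf("<edge_matrix> %d samples x %d edges (state 1: %d, state 2: %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$states == 1L), sum(x$states == 2L)))
  invisible(x)
}

#' @export
dim.edge_matrix <- function(x) dim(x$values)

# z-score a cohort layer against state statistics; rows use their own state's
# mu/sigma. `need` restricts the sigma>0 requirement to the molecules used.
zscore_by_state <- function(matrix, stats, need) {
  need <- unique(need)
  miss <- setdiff(need, rownames(stats$mean))
  if (length(miss)) {
    eq_abort("MissingMoleculeError",
             sprintf("no reference statistics for molecule(s): %s",
                     paste(utils::head(miss, 10), collapse = ", ")),
             molecules = miss)
  }
  states_here <- as.character(sort(unique(matrix$states)))
  for (k in states_here) {
    bad <- need[stats$sd[need, k] == 0]
    if (length(bad)) {
      eq_abort("DegenerateMoleculeError",
               sprintf("molecule '%s' has zero SD in state %s", bad[1], k),
               molecule = bad[1], state = as.integer(k))
    }
  }
  z <- matrix$values[, need, drop = FALSE]
  for (k in states_here) {
    rows <- matrix$states == as.integer(k)
    z[rows, ] <- sweep(sweep(z[rows, , drop = FALSE], 2L, stats$mean[need, k]),
                       2L, stats$sd[need, k], "/")
  }
  z
}

#' Compute edge strengths for a cohort
#'
#' Applies the z-score-product edge transformation to every sample: each
#' sample's kinase and substrate values are standardized against its own
#' state's mean/SD and multiplied.
#'
#' @param protein,phospho [cohort_matrix()] objects (aligned samples).
#' @param edges `"ks_edges"` data.frame from [build_edges()].
#' @param stats Optional list with elements `protein` and `phosphosite`
#'   ([state_stats()] objects); computed from the cohort when `NULL`.
#' @return An [edge_matrix()] (samples x edges, columns in edge-list order).
#' @export
edge_strength <- function(protein, phospho, edges, stats = NULL) {
  check_aligned(protein, phospho)
  if (is.null(stats)) {
    stats <- list(protein = state_stats(protein),
                  phosphosite = state_stats(phospho))
  }
  if (nrow(edges) == 0L) {
    return(edge_matrix(base::matrix(numeric(0), nrow(protein$values), 0,
                                    dimnames = list(sample_ids(protein), NULL)),
                       protein$states))
  }
  zu <- zscore_by_state(protein, stats$protein, edges$kinase_molecule)
  zv <- zscore_by_state(phospho, stats$phosphosite, edges$substrate_molecule)
  vals <- zu[, edges$kinase_molecule, drop = FALSE] *
    zv[, edges$substrate_molecule, drop = FALSE]
  colnames(vals) <- edges$edge_id
  edge_matrix(vals, protein$states)
}

#' Transform a new patient into the edge-feature space
#'
#' Standardizes the patient's values against the FROZEN reference-cohort
#' statistics of the patient's declared state (the reference mean/SD are not
#' re-estimated with the new sample), then forms the edge products. With
#' `pooled = TRUE` the statistics are instead re-estimated from the
#' reference cohort plus the new sample.
#'
#' @param patient A [patient_profile()].
#' @param ref_stats List with `protein` and `phosphosite` [state_stats()]
#'   objects from the reference cohort.
#' @param edges `"ks_edges"` data.frame.
#' @param pooled Re-pool reference statistics with the new sample
#'   (requires `cohort`).
#' @param cohort The reference cohort (list with `protein`, `phosphosite`
#'   [cohort_matrix()] objects); only needed when `pooled = TRUE`.
#' @return Named numeric vector of edge strengths (names = edge ids).
#' @export
transform_new_sample <- function(patient, ref_stats, edges, pooled = FALSE,
                                 cohort = NULL) {
  stopifnot(inherits(patient, "patient_profile"))
  if (pooled) {
    if (is.null(cohort)) {
      eq_abort("ConfigError", "pooled standardization requires the reference cohort")
    }
    augment <- function(cm, vals) {
      common <- intersect(molecule_ids(cm), names(vals))
      cohort_matrix(rbind(cm$values[, common, drop = FALSE],
                          `rownames<-`(base::matrix(vals[common], 1,
                                                    dimnames = list(NULL, common)),
                                       patient$sample_id)),
                    states = c(cm$states, patient$state), layer = cm$layer)
    }
    ref_stats <- list(protein = state_stats(augment(cohort$protein, patient$protein)),
                      phosphosite = state_stats(augment(cohort$phosphosite,
                                                        patient$phosphosite)))
  }
  k <- as.character(patient$state)
  for (layer in c("protein", "phosphosite")) {
    if (!k %in% colnames(ref_stats[[layer]]$mean)) {
      eq_abort("DegenerateStateError",
               sprintf("reference statistics do not cover state %s", k),
               state = patient$state)
    }
  }
  need_u <- edges$kinase_molecule
  need_v <- edges$substrate_molecule
  miss <- c(setdiff(unique(need_u), names(patient$protein)),
            setdiff(unique(need_v), names(patient$phosphosite)))
  if (length(miss)) {
    eq_abort("MissingMoleculeError",
             sprintf("patient profile lacks molecule(s): %s",
                     paste(utils::head(miss, 10), collapse = ", ")),
             molecules = miss)
  }
  z_one <- function(vals, stats, ids) {
    sd_k <- stats$sd[ids, k]
    if (any(sd_k == 0)) {
      bad <- ids[sd_k == 0][1]
      eq_abort("DegenerateMoleculeError",
               sprintf("molecule '%s' has zero SD in state %s", bad, k),
               molecule = bad, state = patient$state)
    }
    (vals[ids] - stats$mean[ids, k]) / sd_k
  }
  out <- z_one(patient$protein, ref_stats$protein, need_u) *
    z_one(patient$phosphosite, ref_stats$phosphosite, need_v)
  names(out) <- edges$edge_id
  out
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p` (two-sided, from `t = r * sqrt((n-2)/(1-r^2))`
#'   on `n - 2` degrees of freedom), `n`, `statistic` and `df`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    eq_abort("DegenerateInputError", "x and y must have equal length")
  }
  n <- length(x)
  if (n < 3L) {
    eq_abort("DegenerateInputError", "need at least 3 paired observations")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    eq_abort("DegenerateInputError", "non-finite values in input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    eq_abort("DegenerateInputError", "zero variance input")
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(r = r, p = p, n = n, statistic = t, df = df)
}

#' Screen differentially correlated kinase-substrate pairs (DCPs)
#'
#' For each candidate (protein molecule, phosphosite molecule) pair, the
#' Pearson correlation is computed separately within state 1 and state 2
#' samples; the difference `delta = r_state1 - r_state2` is tested with the
#' Fisher z transformation (two-sided normal test on
#' `atanh(r1) - atanh(r2)` with SE `sqrt(1/(n1-3) + 1/(n2-3))`). A pair is
#' selected iff `|delta| >= min_abs_delta` and `fisher_z_p <= alpha_level`.
#'
#' @param protein,phospho [cohort_matrix()] objects (aligned samples; both
#'   states need >= 4 samples).
#' @param pairs Two-column data.frame (protein molecule id, phosphosite
#'   molecule id), or a `"ks_edges"` data.frame whose
#'   kinase/substrate molecules define the pairs. `NULL` screens every
#'   protein x phosphosite combination.
#' @param min_abs_delta Minimum absolute correlation difference (default 0.5).
#' @param alpha_level Significance level for the Fisher z test (default 0.05).
#' @return data.frame with columns `protein_id`, `phospho_id`, `r_state1`,
#'   `r_state2`, `delta`, `fisher_z_p`, `selected`. Pairs with a
#'   zero-variance column in either state are reported unselected with `NA`
#'   statistics (with a warning).
#' @export
dcp_screen <- function(protein, phospho, pairs = NULL, min_abs_delta = 0.5,
                       alpha_level = 0.05) {
  check_aligned(protein, phospho)
  check_number(min_abs_delta, "min_abs_delta", lower = 0, upper = 2)
  check_number(alpha_level, "alpha_level", lower = 0, upper = 1)
  n1 <- sum(protein$states == 1L)
  n2 <- sum(protein$states == 2L)
  if (n1 < 4L || n2 < 4L) {
    eq_abort("DegenerateStateError",
             sprintf("Fisher z needs >= 4 samples per state (have %d, %d)", n1, n2),
             n1 = n1, n2 = n2)
  }
  if (is.null(pairs)) {
    pairs <- expand.grid(protein_id = molecule_ids(protein),
                         phospho_id = molecule_ids(phospho),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(pairs, "ks_edges")) {
    pairs <- data.frame(protein_id = pairs$kinase_molecule,
                        phospho_id = pairs$substrate_molecule,
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(protein_id = as.character(pairs[[1]]),
                        phospho_id = as.character(pairs[[2]]),
                        stringsAsFactors = FALSE)
  }
  state_r <- function(k) {
    rows <- protein$states == k
    xp <- protein$values[rows, pairs$protein_id, drop = FALSE]
    xs <- phospho$values[rows, pairs$phospho_id, drop = FALSE]
    sdp <- apply(xp, 2L, stats::sd)
    sds <- apply(xs, 2L, stats::sd)
    r <- colSums(scale(xp) * scale(xs)) / (sum(rows) - 1)
    r[sdp == 0 | sds == 0] <- NA_real_
    unname(r)
  }
  r1 <- state_r(1L)
  r2 <- state_r(2L)
  degenerate <- is.na(r1) | is.na(r2)
  if (any(degenerate)) {
    warning(sprintf("dcp_screen: %d pair(s) skipped for zero within-state variance",
                    sum(degenerate)), call. = FALSE)
  }
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(atanh(r1) - atanh(r2)) / se)
  delta <- r1 - r2
  selected <- !degenerate & abs(delta) >= min_abs_delta & p <= alpha_level
  data.frame(pairs, r_state1 = r1, r_state2 = r2, delta = delta,
             fisher_z_p = p, selected = selected, stringsAsFactors = FALSE)
}
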