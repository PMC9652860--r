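# Edge-biomarker selection: response-correlation pre-filter, then repeated
# random train/test splits with an alpha-grid elastic-net search. For each
# split and each alpha, lambda is chosen by k-fold cross-validation on the
# training part (standard lambda path via glmnet); the training-set fit is
# scored on the held-out part, and the single (split, alpha, lambda) fit with
# the globally smallest test MSE defines the selected edge biomarkers (its
# nonzero-coefficient edges).

#' Selection procedure configuration
#'
#' Defaults follow the published procedure where stated (100 random
#' train/test resamples; alpha searched over a fixed-step grid) and
#' documented conventions elsewhere (test fraction 0.3, 5-fold CV, 100-point
#' lambda path down to `1e-3 * lambda_max`).
#'
#' @param n_splits Number of random train/test resamples (default 100).
#' @param test_fraction Held-out fraction per resample, in (0, 1).
#' @param alpha_grid Ordered elastic-net mixing values in `[0, 1]`
#'   (default 0 to 1 in steps of 0.1).
#' @param cv_folds Cross-validation folds for the lambda choice.
#' @param prefilter_top_m Keep the top-m edges by `|r|` with the response
#'   (`NULL` = off).
#' @param prefilter_min_abs_r Keep edges with `|r| >=` this value
#'   (`NULL` = off). At most one prefilter rule may be set.
#' @param lambda_min_ratio,n_lambda Lambda path geometry.
#' @param rule `"global"` picks the single minimum-MSE (split, alpha) fit;
#'   `"median"` picks the alpha minimizing the median MSE across splits,
#'   then the best split at that alpha.
#' @param stratify Stratify splits on state labels when both states are
#'   present, so no test set is single-state.
#' @param seed Integer RNG seed; fixes the whole procedure.
#' @return Object of class `"selection_config"` (a validated list).
#' @export
selection_config <- function(n_splits = 100L, test_fraction = 0.3,
                             alpha_grid = seq(0, 1, by = 0.1),
                             cv_folds = 5L, prefilter_top_m = NULL,
                             prefilter_min_abs_r = NULL,
                             lambda_min_ratio = 1e-3, n_lambda = 100L,
                             rule = c("global", "median"),
                             stratify = TRUE, seed = 1L) {
  rule <- match.arg(rule)
  n_splits <- check_count(n_splits, "n_splits")
  check_number(test_fraction, "test_fraction", lower = 1e-9, upper = 1 - 1e-9)
  if (length(alpha_grid) == 0L || any(!is.finite(alpha_grid)) ||
      any(alpha_grid < 0 | alpha_grid > 1)) {
    eq_abort("ConfigError", "`alpha_grid` must be a nonempty vector in [0, 1]")
  }
  cv_folds <- check_count(cv_folds, "cv_folds", lower = 3L)
  if (!is.null(prefilter_top_m) && !is.null(prefilter_min_abs_r)) {
    eq_abort("ConfigError",
             "set at most one of prefilter_top_m / prefilter_min_abs_r")
  }
  if (!is.null(prefilter_top_m)) {
    prefilter_top_m <- check_count(prefilter_top_m, "prefilter_top_m")
  }
  if (!is.null(prefilter_min_abs_r)) {
    check_number(prefilter_min_abs_r, "prefilter_min_abs_r", lower = 0, upper = 1)
  }
  check_number(lambda_min_ratio, "lambda_min_ratio", lower = 1e-12, upper = 1)
  n_lambda <- check_count(n_lambda, "n_lambda", lower = 2L)
  seed <- check_count(seed, "seed", lower = 0L)
  structure(list(n_splits = n_splits, test_fraction = test_fraction,
                 alpha_grid = sort(alpha_grid), cv_folds = cv_folds,
                 prefilter_top_m = prefilter_top_m,
                 prefilter_min_abs_r = prefilter_min_abs_r,
                 lambda_min_ratio = lambda_min_ratio, n_lambda = n_lambda,
                 rule = rule, stratify = stratify, seed = seed),
            class = "selection_config")
}

# align a drug's TCGI vector to the edge-matrix samples
drug_response_vector <- function(edge_matrix, responses, drug) {
  if (is.numeric(responses) && !is.null(names(responses))) {
    y <- responses[rownames(edge_matrix$values)]
  } else {
    if (!is.data.frame(responses) || !"sample_id" %in% names(responses)) {
      eq_abort("FormatError", "`responses` must have a sample_id column")
    }
    if (!drug %in% names(responses)) {
      eq_abort("FormatError", sprintf("drug '%s' not in response table", drug))
    }
    y <- responses[[drug]][match(rownames(edge_matrix$values),
                                 responses$sample_id)]
  }
  if (anyNA(y)) {
    eq_abort("MissingSampleError",
             sprintf("no observed TCGI for sample(s): %s",
                     paste(utils::head(rownames(edge_matrix$values)[is.na(y)], 5),
                           collapse = ", ")))
  }
  as.numeric(y)
}

#' Pre-filter edges by correlation with drug response
#'
#' Keeps edges whose absolute Pearson correlation with the observed TCGI
#' passes the configured rule: `|r| >= prefilter_min_abs_r`, or the top-m by
#' `|r|` (ties broken by `|r|` descending then edge id ascending, so the
#' result is deterministic). With both rules unset the matrix is returned
#' unchanged.
#'
#' @param edge_matrix An [edge_matrix()].
#' @param responses Response table (data.frame with `sample_id` + drug
#'   columns) or a named numeric vector.
#' @param drug Drug name.
#' @param config A [selection_config()].
#' @return The reduced [edge_matrix()], with the per-edge correlations in
#'   attribute `"response_r"`.
#' @export
prefilter_by_response <- function(edge_matrix, responses, drug,
                                  config = selection_config()) {
  y <- drug_response_vector(edge_matrix, responses, drug)
  if (is.null(config$prefilter_top_m) && is.null(config$prefilter_min_abs_r)) {
    return(edge_matrix)
  }
  x <- edge_matrix$values
  sds <- apply(x, 2L, stats::sd)
  r <- rep(0, ncol(x))
  ok <- sds > 0 & stats::sd(y) > 0
  r[ok] <- drop(stats::cor(x[, ok, drop = FALSE], y))
  names(r) <- colnames(x)
  if (!is.null(config$prefilter_min_abs_r)) {
    keep <- which(abs(r) >= config$prefilter_min_abs_r)
  } else {
    ord <- order(-abs(r), colnames(x))
    keep <- sort(ord[seq_len(min(config$prefilter_top_m, ncol(x)))])
  }
  if (length(keep) == 0L) {
    eq_abort("EmptyFeatureSetError",
             "no edge passes the response-correlation pre-filter")
  }
  out <- edge_matrix(x[, keep, drop = FALSE], edge_matrix$states)
  attr(out, "response_r") <- r[keep]
  out
}

# deterministic, optionally state-stratified test-index draw
draw_test_indices <- function(states, test_fraction, stratify) {
  n <- length(states)
  if (stratify && length(unique(states)) > 1L) {
    unlist(lapply(sort(unique(states)), function(k) {
      idx <- which(states == k)
      sample(idx, max(1L, round(test_fraction * length(idx))))
    }), use.names = FALSE)
  } else {
    sample(n, max(1L, round(test_fraction * n)))
  }
}

#' Select edge biomarkers by repeated-split elastic net
#'
#' Runs the repeated-resampling search described in
#' [selection_config()]: for each of `n_splits` random train/test
#' partitions and each alpha on the grid, lambda is chosen by
#' `cv_folds`-fold cross-validation on the training part, the training fit
#' is evaluated on the test part, and the minimum-test-MSE fit defines the
#' selected edge set. The full (split, alpha) trace is retained. The whole
#' procedure is a deterministic function of `config$seed`.
#'
#' @inheritParams prefilter_by_response
#' @return Object of class `"edge_selection"`: list with
#'   `selected_edge_ids`, `coefficients` (of the winning fit, original
#'   edge-strength scale), `best_alpha`, `best_lambda`, `best_mse`,
#'   `best_split`, `trace` (data.frame: split, alpha, lambda, mse,
#'   n_nonzero), `candidate_edge_ids`, `drug`, `config` and `seed`.
#' @export
select_edge_biomarkers <- function(edge_matrix, responses, drug,
                                   config = selection_config()) {
  stopifnot(inherits(edge_matrix, "edge_matrix"))
  if (!inherits(config, "selection_config")) {
    eq_abort("ConfigError", "`config` must come from selection_config()")
  }
  em <- prefilter_by_response(edge_matrix, responses, drug, config)
  y <- drug_response_vector(em, responses, drug)
  x <- em$values
  n <- nrow(x)
  p <- ncol(x)
  if (p < 1L) eq_abort("EmptyFeatureSetError", "no candidate edges")
  if (n < config$cv_folds + 2L) {
    eq_abort("ConfigError",
             sprintf("need >= cv_folds + 2 = %d samples, have %d",
                     config$cv_folds + 2L, n))
  }
  # glmnet needs >= 2 predictors; pad a null column that can never be chosen
  padded <- p == 1L
  if (padded) x <- cbind(x, `.null.pad` = 0)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  trace <- vector("list", config$n_splits * length(config$alpha_grid))
  row_i <- 0L
  best <- list(mse = Inf)
  for (s in seq_len(config$n_splits)) {
    test_idx <- draw_test_indices(em$states, config$test_fraction,
                                  config$stratify)
    train_idx <- setdiff(seq_len(n), test_idx)
    foldid <- sample(rep_len(seq_len(config$cv_folds), length(train_idx)))
    for (a in config$alpha_grid) {
      cvfit <- glmnet::cv.glmnet(
        x[train_idx, , drop = FALSE], y[train_idx], alpha = a,
        foldid = foldid, nlambda = config$n_lambda,
        lambda.min.ratio = config$lambda_min_ratio,
        standardize = TRUE, family = "gaussian")
      pred <- drop(stats::predict(cvfit, newx = x[test_idx, , drop = FALSE],
                                  s = "lambda.min"))
      mse <- mean((y[test_idx] - pred)^2)
      cf <- drop(as.matrix(stats::coef(cvfit, s = "lambda.min")))
      beta <- cf[-1]
      if (padded) beta <- beta[names(beta) != ".null.pad"]
      row_i <- row_i + 1L
      trace[[row_i]] <- data.frame(split = s, alpha = a,
                                   lambda = cvfit$lambda.min, mse = mse,
                                   n_nonzero = sum(beta != 0))
      if (mse < best$mse) {
        best <- list(mse = mse, alpha = a, lambda = cvfit$lambda.min,
                     split = s, intercept = unname(cf[1]),
                     beta = beta[beta != 0])
      }
    }
  }
  trace <- do.call(rbind, trace)
  if (config$rule == "median") {
    med <- tapply(trace$mse, trace$alpha, stats::median)
    a_star <- as.numeric(names(med)[which.min(med)])
    sub <- trace[trace$alpha == a_star, , drop = FALSE]
    # winner = best split at the median-optimal alpha; refit to recover it
    best_row <- sub[which.min(sub$mse), ]
    best <- refit_trace_row(x, y, em$states, config, best_row, padded)
  }
  selected <- names(best$beta)
  if (length(selected) == 0L) {
    eq_abort("EmptyFeatureSetError",
             "the minimum-MSE fit has no nonzero coefficients", trace = trace)
  }
  structure(list(selected_edge_ids = selected,
                 coefficients = best$beta,
                 best_alpha = best$alpha, best_lambda = best$lambda,
                 best_mse = best$mse, best_split = best$split,
                 trace = trace, candidate_edge_ids = colnames(em$values),
                 drug = drug, config = config, seed = config$seed),
            class = "edge_selection")
}

# re-run the RNG stream up to a given split to recover its fit (median rule)
refit_trace_row <- function(x, y, states, config, row, padded) {
  set.seed(config$seed)
  for (s in seq_len(row$split)) {
    test_idx <- draw_test_indices(states, config$test_fraction, config$stratify)
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    foldid <- sample(rep_len(seq_len(config$cv_folds), length(train_idx)))
    if (s < row$split) {
      next
    }
    cvfit <- glmnet::cv.glmnet(
      x[train_idx, , drop = FALSE], y[train_idx], alpha = row$alpha,
      foldid = foldid, nlambda = config$n_lambda,
      lambda.min.ratio = config$lambda_min_ratio,
      standardize = TRUE, family = "gaussian")
    cf <- drop(as.matrix(stats::coef(cvfit, s = "lambda.min")))
    beta <- cf[-1]
    if (padded) beta <- beta[names(beta) != ".null.pad"]
    return(list(mse = row$mse, alpha = row$alpha, lambda = cvfit$lambda.min,
                split = row$split, intercept = unname(cf[1]),
                beta = beta[beta != 0]))
  }
}

#' @export
print.edge_selection <- function(x, ...) {
  cat(sprintf("<edge_selection> drug '%s': %d / %d edges selected\n",
              x$drug, length(x$selected_edge_ids),
              length(x$candidate_edge_ids)))
  cat(sprintf("  best fit: split %d, alpha = %.2f, lambda = %.4g, test MSE = %.4g\n",
              x$best_split, x$best_alpha, x$best_lambda, x$best_mse))
  cat(sprintf("  trace: %d (split, alpha) fits, seed %d\n",
              nrow(x$trace), x$seed))
  invisible(x)
}

#' Save / load a selection result as JSON (including the full trace)
#'
#' @param selection An `"edge_selection"` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_selection <- function(selection, path) {
  stopifnot(inherits(selection, "edge_selection"))
  doc <- list(schema_version = 1L,
              drug = selection$drug,
              selected_edge_ids = as.list(selection$selected_edge_ids),
              coefficients = as.list(unname(selection$coefficients)),
              best_alpha = selection$best_alpha,
              best_lambda = selection$best_lambda,
              best_mse = selection$best_mse,
              best_split = selection$best_split,
              seed = selection$seed,
              candidate_edge_ids = as.list(selection$candidate_edge_ids),
              config = unclass(selection$config),
              trace = selection$trace)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}
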