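# Final per-drug model: an elastic-net linear model over the selected edge
# strengths, fitted by the package's own coordinate-descent solver so the
# returned coefficients satisfy the KKT conditions of the stated objective.
# Features are standardized internally (training mean/SD); coefficients are
# reported back on the original edge-strength scale and the scaling
# constants are stored, so a saved model predicts self-contained.

new_drug_model <- function(drug, alpha, lambda, intercept, coefficients,
                           training_meta) {
  structure(list(drug = drug, alpha = alpha, lambda = lambda,
                 intercept = intercept,
                 features = names(coefficients),
                 coefficients = coefficients,
                 training_meta = training_meta),
            class = "drug_model")
}

#' Fit the final per-drug elastic-net model
#'
#' Refits an elastic net at a fixed (alpha, lambda) — typically the winner
#' of [select_edge_biomarkers()] — on all cohort samples, restricted to the
#' selected edge features. Internally, features are standardized and the
#' response is scaled to unit variance, so `lambda` carries the same
#' (dimensionless) meaning as in the cross-validated search that chose it;
#' the returned intercept and coefficients are mapped back to the raw TCGI
#' and edge-strength scales, and the KKT residual of the solved problem is
#' stored in `training_meta$kkt`.
#'
#' @param edge_matrix An [edge_matrix()] (or plain numeric matrix with
#'   dimnames).
#' @param responses Response table (data.frame with `sample_id` + drug
#'   columns) or named numeric vector of observed TCGI.
#' @param drug Drug name.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @param lambda Penalty, `>= 0`.
#' @param features Edge ids to use (default: all columns).
#' @param seed Recorded in `training_meta` (the fit itself is deterministic).
#' @return Object of class `"drug_model"` with `print()`, `summary()`,
#'   `coef()` and `predict()` methods.
#' @export
fit_drug_model <- function(edge_matrix, responses, drug, alpha, lambda,
                           features = NULL, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    eq_abort("ConfigError", "alpha must be in [0, 1]")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0) {
    eq_abort("ConfigError", "lambda must be >= 0")
  }
  x_all <- if (inherits(edge_matrix, "edge_matrix")) edge_matrix$values
           else as.matrix(edge_matrix)
  if (inherits(edge_matrix, "edge_matrix")) {
    y <- drug_response_vector(edge_matrix, responses, drug)
  } else {
    y <- drug_response_vector(list(values = x_all), responses, drug)
  }
  if (is.null(features)) features <- colnames(x_all)
  if (length(features) == 0L) {
    eq_abort("EmptyFeatureSetError", "no features to fit")
  }
  miss <- setdiff(features, colnames(x_all))
  if (length(miss)) {
    eq_abort("MissingMoleculeError",
             sprintf("edge matrix lacks feature(s): %s",
                     paste(utils::head(miss, 10), collapse = ", ")),
             molecules = miss)
  }
  x <- x_all[, features, drop = FALSE]
  n <- nrow(x)
  if (n < 2L) eq_abort("ConfigError", "need >= 2 samples")
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ == 0] <- 1  # constant feature: centered to zero, coef stays 0
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  # response scaled to unit variance (1/n), the same convention under which
  # the cross-validated search interprets lambda; coefficients are mapped
  # back to the raw TCGI / edge-strength scales below
  sy <- sqrt(mean((y - mean(y))^2))
  if (sy == 0) sy <- 1
  fit <- enet_fit(xs, y / sy, alpha = alpha, lambda = lambda)
  beta_orig <- fit$coefficients * sy / scale_
  intercept_orig <- fit$intercept * sy - sum(beta_orig * center)
  names(beta_orig) <- features
  new_drug_model(
    drug = drug, alpha = alpha, lambda = lambda,
    intercept = intercept_orig, coefficients = beta_orig,
    training_meta = list(n_samples = n, seed = seed,
                         center = unname(center), scale = unname(scale_),
                         response_scale = sy, kkt = fit$kkt,
                         intercept_standardized = fit$intercept))
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("<drug_model> drug '%s': %d features, alpha = %.2f, lambda = %.4g\n",
              x$drug, length(x$features), x$alpha, x$lambda))
  cat(sprintf("  intercept %.4g, %d nonzero coefficient(s), trained on %s samples\n",
              x$intercept, sum(x$coefficients != 0),
              x$training_meta$n_samples %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.drug_model <- function(object, ...) {
  cf <- object$coefficients
  df <- data.frame(edge_id = object$features, coefficient = unname(cf))
  df <- df[order(-abs(df$coefficient)), ]
  rownames(df) <- NULL
  out <- list(drug = object$drug, alpha = object$alpha,
              lambda = object$lambda, intercept = object$intercept,
              coefficients = df,
              n_nonzero = sum(cf != 0),
              training_meta = object$training_meta)
  class(out) <- "summary.drug_model"
  out
}

#' @export
print.summary.drug_model <- function(x, ...) {
  cat(sprintf("Elastic-net TCGI model for drug '%s'\n", x$drug))
  cat(sprintf("  alpha = %.2f, lambda = %.4g, intercept = %.4g\n",
              x$alpha, x$lambda, x$intercept))
  cat(sprintf("  %d feature(s), %d with nonzero coefficient:\n",
              nrow(x$coefficients), x$n_nonzero))
  print(utils::head(x$coefficients[x$coefficients$coefficient != 0, ], 20))
  invisible(x)
}

#' @export
coef.drug_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict TCGI for new samples
#'
#' @param object A `"drug_model"`.
#' @param newdata An [edge_matrix()], a numeric matrix (samples x edges,
#'   named columns), or a single named edge-strength vector from
#'   [transform_new_sample()]. All model features must be present.
#' @param ... Unused.
#' @return Numeric vector of predicted TCGI (percent), one per sample. Not
#'   clipped to `[0, 100]`.
#' @export
predict.drug_model <- function(object, newdata, ...) {
  if (inherits(newdata, "edge_matrix")) newdata <- newdata$values
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    eq_abort("MissingMoleculeError",
             sprintf("new data lacks model feature(s): %s",
                     paste(utils::head(miss, 10), collapse = ", ")),
             molecules = miss)
  }
  drop(object$intercept +
         newdata[, object$features, drop = FALSE] %*% object$coefficients)
}

#' Evaluate predicted against observed TCGI
#'
#' Pearson correlation between predictions and observations, with the
#' two-sided t-based p-value; `r_squared` is the squared Pearson
#' correlation (sign-blind), and the coefficient of determination
#' `1 - SS_res/SS_tot` is reported separately since the two differ for
#' biased predictions.
#'
#' @param predicted,observed Numeric vectors of equal length >= 3.
#' @return Object of class `"tcgi_evaluation"`: list with `n`, `pearson_r`,
#'   `r_squared`, `p_value`, `r_squared_cod` and `pairs`
#'   (data.frame of observed/predicted).
#' @export
evaluate_predictions <- function(predicted, observed) {
  pc <- pearson_cor(predicted, observed)
  cod <- 1 - sum((observed - predicted)^2) /
    sum((observed - mean(observed))^2)
  structure(list(n = pc$n, pearson_r = pc$r, r_squared = pc$r^2,
                 p_value = pc$p, r_squared_cod = cod,
                 pairs = data.frame(observed = observed,
                                    predicted = predicted)),
            class = "tcgi_evaluation")
}

#' @export
print.tcgi_evaluation <- function(x, ...) {
  cat(sprintf("<tcgi_evaluation> n = %d: R-squared %.3f (Pearson r %.3f), p = %.3g\n",
              x$n, x$r_squared, x$pearson_r, x$p_value))
  cat(sprintf("  coefficient of determination: %.3f\n", x$r_squared_cod))
  invisible(x)
}
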