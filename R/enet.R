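# Elastic-net solver for the final per-drug fits.
#
# Objective (the canonical parameterization):
#   (1/(2n)) * sum((y - b0 - X b)^2) + lambda * (alpha*||b||_1 + ((1-alpha)/2)*||b||_2^2)
#
# Solved by cyclic coordinate descent with an unpenalized intercept. The
# solver iterates until the subgradient (KKT) residual is below `kkt_tol`,
# so fitted coefficients certify their own optimality; the repeated-split
# feature-selection search uses glmnet instead (same objective family) for
# speed, and glmnet serves as an independent cross-check of this solver in
# the test suite.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit one elastic-net problem by coordinate descent
#'
#' @param x Numeric n x p predictor matrix (used as given; no internal
#'   standardization).
#' @param y Numeric response vector, length n.
#' @param alpha Mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Overall penalty, `>= 0`.
#' @param tol Convergence tolerance on the maximum coefficient update.
#' @param kkt_tol Required subgradient residual at the solution.
#' @param max_iter Sweep cap.
#' @param beta_init,intercept_init Optional warm start.
#' @return List with `intercept`, `coefficients` (named by column), `alpha`,
#'   `lambda`, `kkt` (achieved residual) and `iterations`.
#' @export
enet_fit <- function(x, y, alpha, lambda, tol = 1e-12, kkt_tol = 1e-8,
                     max_iter = 100000L, beta_init = NULL,
                     intercept_init = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n || n < 2L) {
    eq_abort("ConfigError", "need length(y) == nrow(x) >= 2")
  }
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(lambda, "lambda", lower = 0)
  xsq <- colSums(x^2) / n
  denom <- xsq + lambda * (1 - alpha)
  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)
  b0 <- if (is.null(intercept_init)) mean(y) else intercept_init
  r <- y - b0 - drop(x %*% beta)
  thr <- lambda * alpha
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta_max <- 0
    new_b0 <- b0 + mean(r)
    r <- r - (new_b0 - b0)
    delta_max <- max(delta_max, abs(new_b0 - b0))
    b0 <- new_b0
    for (j in seq_len(p)) {
      if (denom[j] == 0) next  # all-zero predictor column
      bj <- beta[j]
      rho <- sum(x[, j] * r) / n + xsq[j] * bj
      bj_new <- soft_threshold(rho, thr) / denom[j]
      if (bj_new != bj) {
        r <- r - x[, j] * (bj_new - bj)
        beta[j] <- bj_new
        delta_max <- max(delta_max, abs(bj_new - bj))
      }
    }
    if (delta_max < tol * max(1, max(abs(beta)), abs(b0))) {
      kkt <- enet_kkt(x, y, b0, beta, alpha, lambda)
      if (kkt <= kkt_tol || iter >= max_iter) break
    }
    if (iter >= max_iter) {
      kkt <- enet_kkt(x, y, b0, beta, alpha, lambda)
      break
    }
  }
  names(beta) <- colnames(x)
  list(intercept = b0, coefficients = beta, alpha = alpha, lambda = lambda,
       kkt = kkt, iterations = iter)
}

#' Subgradient (KKT) residual of an elastic-net solution
#'
#' Maximum violation of the stationarity conditions of the objective: for
#' nonzero coordinates `|g_j - lambda*(1-alpha)*b_j - lambda*alpha*sign(b_j)|`,
#' for zero coordinates `max(0, |g_j| - lambda*alpha)`, plus `|mean residual|`
#' for the intercept, where `g_j = x_j' r / n`.
#'
#' @inheritParams enet_fit
#' @param intercept,beta Candidate solution.
#' @return Maximum absolute violation (0 at an exact optimum).
#' @export
enet_kkt <- function(x, y, intercept, beta, alpha, lambda) {
  x <- as.matrix(x)
  n <- nrow(x)
  r <- y - intercept - drop(x %*% beta)
  g <- drop(crossprod(x, r)) / n
  nz <- beta != 0
  viol <- numeric(length(beta))
  viol[nz] <- abs(g[nz] - lambda * (1 - alpha) * beta[nz] -
                    lambda * alpha * sign(beta[nz]))
  viol[!nz] <- pmax(0, abs(g[!nz]) - lambda * alpha)
  max(abs(mean(r)), viol)
}

#' Elastic-net regularization path with warm starts
#'
#' Fits [enet_fit()] along a decreasing log-spaced lambda sequence from
#' `lambda_max` (the smallest lambda zeroing every coefficient) down to
#' `lambda_max * lambda_min_ratio`, warm-starting each fit at the previous
#' solution.
#'
#' @inheritParams enet_fit
#' @param nlambda Number of grid points (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest lambda (default 1e-3).
#' @param lambda Optional explicit decreasing lambda sequence.
#' @return List with `lambda`, `intercept` (vector), `beta` (p x nlambda
#'   matrix), `kkt` (per-lambda residuals).
#' @export
enet_path <- function(x, y, alpha, nlambda = 100L, lambda_min_ratio = 1e-3,
                      lambda = NULL, tol = 1e-12, kkt_tol = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(lambda)) {
    # for alpha near 0 lambda_max diverges; cap as in standard practice
    a_eff <- max(alpha, 1e-3)
    lambda_max <- max(abs(drop(crossprod(x, y - mean(y)))) / n) / a_eff
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  p <- ncol(x)
  beta <- matrix(0, p, length(lambda),
                 dimnames = list(colnames(x), NULL))
  b0 <- kkt <- numeric(length(lambda))
  warm <- NULL
  warm_b0 <- NULL
  for (i in seq_along(lambda)) {
    fit <- enet_fit(x, y, alpha, lambda[i], tol = tol, kkt_tol = kkt_tol,
                    beta_init = warm, intercept_init = warm_b0)
    beta[, i] <- fit$coefficients
    b0[i] <- fit$intercept
    kkt[i] <- fit$kkt
    warm <- fit$coefficients
    warm_b0 <- fit$intercept
  }
  list(lambda = lambda, intercept = b0, beta = beta, kkt = kkt, alpha = alpha)
}
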