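# Response-correlation pre-filter and the repeated-split selection loop.

test_that("configuration defaults follow the documented procedure", {
  cfg <- selection_config()
  expect_identical(cfg$n_splits, 100L)
  expect_equal(cfg$test_fraction, 0.3)
  expect_equal(cfg$alpha_grid, seq(0, 1, by = 0.1))
  expect_identical(cfg$cv_folds, 5L)
  expect_equal(cfg$lambda_min_ratio, 1e-3)
  expect_identical(cfg$n_lambda, 100L)
  expect_identical(cfg$rule, "global")
  expect_error(selection_config(n_splits = 0), class = "ConfigError")
  expect_error(selection_config(alpha_grid = c(0.5, 2)), class = "ConfigError")
  expect_error(selection_config(prefilter_top_m = 3, prefilter_min_abs_r = 0.2),
               class = "ConfigError")
})

test_that("response pre-filter keeps the right edges deterministically", {
  set.seed(10)
  n <- 24
  y <- rnorm(n)
  vals <- matrix(rnorm(n * 10), n, 10,
                 dimnames = list(sprintf("S%02d", 1:n), sprintf("E%02d", 1:10)))
  vals[, 4] <- y  # perfectly correlated edge
  em <- edge_matrix(vals, rep(c(1L, 2L), each = 12))
  names(y) <- rownames(vals)

  # |r| = 1 edge always survives a threshold filter
  kept <- prefilter_by_response(em, y, "d",
                                selection_config(prefilter_min_abs_r = 0.9))
  expect_true("E04" %in% colnames(kept$values))

  # disabled filter is the identity
  expect_identical(prefilter_by_response(em, y, "d", selection_config()), em)

  # top-m agrees with a brute-force ranking oracle
  r_all <- apply(vals, 2, function(e) cor(e, y))
  oracle <- colnames(vals)[order(-abs(r_all), colnames(vals))][1:3]
  kept3 <- prefilter_by_response(em, y, "d",
                                 selection_config(prefilter_top_m = 3))
  expect_setequal(colnames(kept3$values), oracle)
  # column order of the original matrix is preserved
  expect_identical(colnames(kept3$values),
                   colnames(vals)[colnames(vals) %in% oracle])
  # nothing survives a threshold no noisy edge can reach
  em_noise <- edge_matrix(vals[, -4], rep(c(1L, 2L), each = 12))
  expect_error(prefilter_by_response(em_noise, y, "d",
                                     selection_config(prefilter_min_abs_r = 1)),
               class = "EmptyFeatureSetError")
})

test_that("a single informative edge is selected with near-noise MSE", {
  set.seed(3)
  n <- 60
  e <- rnorm(n)
  y <- 3 * e + rnorm(n, sd = 0.1)
  em <- edge_matrix(matrix(e, n, 1, dimnames = list(sprintf("S%02d", 1:n), "K->G_S1")),
                    rep(c(1L, 2L), each = 30))
  names(y) <- rownames(em$values)
  sel <- select_edge_biomarkers(em, y, "d",
                                selection_config(n_splits = 5,
                                                 alpha_grid = c(0.5, 1), seed = 4))
  expect_identical(sel$selected_edge_ids, "K->G_S1")
  expect_lt(sel$best_mse, 0.05)   # about the injected noise variance (0.01)
})

test_that("selection is a deterministic function of the seed", {
  co <- generate_cohort(synth_config(seed = 6))
  em <- edge_strength(co$protein, co$phosphosite,
                      build_edges(co$relations, co$protein, co$phosphosite))
  cfg <- selection_config(n_splits = 4, alpha_grid = c(0.5, 1), seed = 17)
  s1 <- select_edge_biomarkers(em, co$responses, "drug1", cfg)
  s2 <- select_edge_biomarkers(em, co$responses, "drug1", cfg)
  expect_identical(s1, s2)
  s3 <- select_edge_biomarkers(em, co$responses, "drug1",
                               selection_config(n_splits = 4,
                                                alpha_grid = c(0.5, 1), seed = 18))
  expect_false(identical(s1$trace, s3$trace))
  # best_mse is the minimum of the trace; coefficients cover the selection
  expect_equal(s1$best_mse, min(s1$trace$mse))
  expect_setequal(names(s1$coefficients), s1$selected_edge_ids)
})

test_that("planted edges are recovered and pure noise is not overfit", {
  # light version of the recovery study (the acceptance suite runs it in full)
  hits <- vapply(1:5, function(seed) {
    co <- generate_cohort(synth_config(n_samples = 40, seed = seed))
    em <- edge_strength(co$protein, co$phosphosite,
                        build_edges(co$relations, co$protein, co$phosphosite))
    sel <- select_edge_biomarkers(em, co$responses, "drug1",
                                  selection_config(n_splits = 5,
                                                   alpha_grid = c(0.5, 1),
                                                   seed = seed))
    score_recovery(sel, co$truth)$sensitivity
  }, numeric(1))
  expect_true(all(hits == 1))

  # null responses: held-out MSE stays on the order of the response variance
  set.seed(40)
  co <- generate_cohort(synth_config(n_samples = 40, n_informative_edges = 0,
                                     true_coefficients = numeric(0),
                                     noise_sd_response = 1, seed = 40))
  em <- edge_strength(co$protein, co$phosphosite,
                      build_edges(co$relations, co$protein, co$phosphosite))
  sel <- tryCatch(
    select_edge_biomarkers(em, co$responses, "drug1",
                           selection_config(n_splits = 5,
                                            alpha_grid = c(0.5, 1), seed = 40)),
    EmptyFeatureSetError = function(e) NULL)
  if (!is.null(sel)) {
    v <- var(co$responses$drug1)
    expect_gt(sel$best_mse, 0.2 * v)
    expect_lt(mean(sel$trace$mse), 3 * v)
  }
})

test_that("median-MSE aggregation rule is available and reproducible", {
  co <- generate_cohort(synth_config(seed = 9))
  em <- edge_strength(co$protein, co$phosphosite,
                      build_edges(co$relations, co$protein, co$phosphosite))
  cfg <- selection_config(n_splits = 4, alpha_grid = c(0.5, 1),
                          rule = "median", seed = 2)
  s1 <- select_edge_biomarkers(em, co$responses, "drug1", cfg)
  s2 <- select_edge_biomarkers(em, co$responses, "drug1", cfg)
  expect_identical(s1, s2)
  med <- tapply(s1$trace$mse, s1$trace$alpha, median)
  expect_equal(s1$best_alpha, as.numeric(names(med)[which.min(med)]))
})
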