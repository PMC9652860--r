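# State statistics, the z-score-product transformation and its invariants,
# Pearson utilities and the DCP screen.

test_that("state statistics use the sample SD per state", {
  m <- cohort_matrix(matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("S", 1:3), "M")),
                     rep(1L, 3), "protein")
  st <- state_stats(m)
  expect_equal(st$mean["M", "1"], 2)
  expect_equal(st$sd["M", "1"], 1)

  m2 <- cohort_matrix(matrix(c(1, 3, 10, 14), 4, 1,
                             dimnames = list(paste0("S", 1:4), "M")),
                      c(1L, 1L, 2L, 2L), "protein")
  st2 <- state_stats(m2)
  expect_equal(st2$mean["M", "1"], 2)
  expect_equal(st2$sd["M", "1"], sqrt(2))
  expect_equal(st2$mean["M", "2"], 12)
  expect_equal(st2$sd["M", "2"], sqrt(8))
  expect_identical(unname(st2$n), c(2L, 2L))

  const <- cohort_matrix(matrix(c(5, 5, 5, 1, 2, 3), 3, 2,
                                dimnames = list(paste0("S", 1:3), c("C", "V"))),
                         rep(1L, 3), "protein")
  expect_warning(stc <- state_stats(const), "constant")
  expect_identical(stc$constant, "C")
  expect_equal(stc$sd["C", "1"], 0)

  one <- cohort_matrix(matrix(c(1, 2, 3), 3, 1,
                              dimnames = list(paste0("S", 1:3), "M")),
                       c(1L, 1L, 2L), "protein")
  expect_error(state_stats(one), class = "DegenerateStateError")
})

test_that("edge strengths are products of within-state z-scores", {
  ids <- paste0("S", 1:3)
  prot <- cohort_matrix(matrix(c(1, 2, 3), 3, 1, dimnames = list(ids, "K")),
                        rep(1L, 3), "protein")
  phos <- cohort_matrix(matrix(c(2, 4, 6), 3, 1, dimnames = list(ids, "G_S1")),
                        rep(1L, 3), "phosphosite")
  edges <- build_edges(data.frame(kinase = "K", substrate_gene = "G",
                                  substrate_site = "S1", source = "t"),
                       prot, phos)
  em <- edge_strength(prot, phos, edges)
  expect_equal(unname(em$values[, 1]), c(1, 0, 1))
  # a sample at the kinase mean gives strength 0 whatever the substrate
  expect_equal(em$values["S2", 1], 0)

  # zero-SD molecule is a typed error
  constp <- cohort_matrix(matrix(c(1, 1, 1), 3, 1, dimnames = list(ids, "K")),
                          rep(1L, 3), "protein")
  suppressWarnings(
    expect_error(edge_strength(constp, phos, edges), class = "DegenerateMoleculeError"))
})

test_that("within-state strength sums equal (n_k - 1) times Pearson r", {
  for (seed in 1:10) {
    co <- random_cohort(n = 14 + seed, seed = seed)
    e <- build_edges(co$relations, co$protein, co$phosphosite)
    em <- edge_strength(co$protein, co$phosphosite, e)
    for (k in 1:2) {
      rows <- em$states == k
      sums <- colSums(em$values[rows, , drop = FALSE])
      r <- mapply(function(u, v) cor(co$protein$values[rows, u],
                                     co$phosphosite$values[rows, v]),
                  e$kinase_molecule, e$substrate_molecule)
      expect_lt(max(abs(sums - (sum(rows) - 1) * r)), 1e-10)
    }
  }
})

test_that("edge strengths are invariant to positive affine rescaling and flip sign under negation", {
  co <- random_cohort(n = 18, seed = 21)
  e <- build_edges(co$relations, co$protein, co$phosphosite)
  em <- edge_strength(co$protein, co$phosphosite, e)
  mol <- e$kinase_molecule[1]
  vals <- co$protein$values
  vals[, mol] <- 2.7 * vals[, mol] + 13          # a > 0
  co2 <- cohort_matrix(vals, co$states, "protein")
  em2 <- edge_strength(co2, co$phosphosite, e)
  expect_lt(max(abs(em2$values - em$values)), 1e-10)

  vals[, mol] <- -co$protein$values[, mol]        # a < 0
  co3 <- cohort_matrix(vals, co$states, "protein")
  em3 <- edge_strength(co3, co$phosphosite, e)
  uses <- e$kinase_molecule == mol
  expect_equal(em3$values[, uses], -em$values[, uses])
  expect_equal(em3$values[, !uses], em$values[, !uses])
})

test_that("a new sample is standardized against frozen reference statistics", {
  co <- random_cohort(n = 16, seed = 8)
  e <- build_edges(co$relations, co$protein, co$phosphosite)
  stats <- list(protein = state_stats(co$protein),
                phosphosite = state_stats(co$phosphosite))
  em <- edge_strength(co$protein, co$phosphosite, e, stats)

  # a patient identical to a training sample reproduces that sample's row
  j <- 3L
  pt <- patient_profile(co$protein$values[j, ], co$phosphosite$values[j, ],
                        "pt", state = co$states[j])
  v <- transform_new_sample(pt, stats, e)
  expect_equal(unname(v), unname(em$values[j, ]), tolerance = 1e-12)

  # a patient at the reference means maps to the zero vector
  pt0 <- patient_profile(stats$protein$mean[, "1"],
                         stats$phosphosite$mean[, "1"], "pt0", state = 1)
  expect_equal(unname(transform_new_sample(pt0, stats, e)),
               rep(0, nrow(e)))

  # kinase at mu + sigma and substrate at mu + 2 sigma gives strength 2
  pt2 <- patient_profile(stats$protein$mean[, "2"] + stats$protein$sd[, "2"],
                         stats$phosphosite$mean[, "2"] +
                           2 * stats$phosphosite$sd[, "2"], "pt2", state = 2)
  expect_equal(unname(transform_new_sample(pt2, stats, e)),
               rep(2, nrow(e)))

  # typed errors: missing molecule, unknown state
  ptm <- patient_profile(pt$protein[-1], pt$phosphosite, "ptm", 1)
  miss <- e$kinase_molecule %in% names(pt$protein)[1]
  if (any(miss)) {
    expect_error(transform_new_sample(ptm, stats, e),
                 class = "MissingMoleculeError")
  }
  stats1 <- list(protein = state_stats(cohort_matrix(
                   co$protein$values[co$states == 1, ], rep(1L, sum(co$states == 1)),
                   "protein")),
                 phosphosite = state_stats(cohort_matrix(
                   co$phosphosite$values[co$states == 1, ], rep(1L, sum(co$states == 1)),
                   "phosphosite")))
  pt_s2 <- patient_profile(co$protein$values[2, ], co$phosphosite$values[2, ],
                           "p", state = 2)
  expect_error(transform_new_sample(pt_s2, stats1, e),
               class = "DegenerateStateError")
})

test_that("pooled standardization re-estimates statistics with the new sample", {
  co <- random_cohort(n = 16, seed = 12)
  e <- build_edges(co$relations, co$protein, co$phosphosite)
  stats <- list(protein = state_stats(co$protein),
                phosphosite = state_stats(co$phosphosite))
  pt <- patient_profile(co$protein$values[1, ] + 1,
                        co$phosphosite$values[1, ] + 1, "pt", 1)
  frozen <- transform_new_sample(pt, stats, e)
  pooled <- transform_new_sample(pt, stats, e, pooled = TRUE,
                                 cohort = list(protein = co$protein,
                                               phosphosite = co$phosphosite))
  expect_false(isTRUE(all.equal(frozen, pooled)))
  # pooled is still deterministic
  expect_identical(pooled,
                   transform_new_sample(pt, stats, e, pooled = TRUE,
                                        cohort = list(protein = co$protein,
                                                      phosphosite = co$phosphosite)))
})

test_that("pearson_cor matches the closed-form t distribution and cor.test", {
  x <- 1:10
  pc <- pearson_cor(x, 2 * x + 1)
  expect_equal(pc$r, 1)
  expect_equal(pc$p, 0)
  expect_equal(pearson_cor(x, -x)$r, -1)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n) + 0.3 * a
    pc <- pearson_cor(a, b)
    ct <- cor.test(a, b)               # independent implementation
    expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_cor(1:2, 1:2), class = "DegenerateInputError")
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), class = "DegenerateInputError")
})

test_that("pearson p-values agree with a permutation null", {
  # instance size keeps the O(1/n) gap between the conditional permutation
  # null and the unconditional t null inside the Monte-Carlo band
  set.seed(77)
  B <- 20000L
  for (i in 1:4) {
    n <- 100L
    x <- rnorm(n); y <- rnorm(n) + 0.4 * x
    pc <- pearson_cor(x, y)
    xs <- (x - mean(x)) / sd(x)
    ys <- (y - mean(y)) / sd(y)
    perm <- matrix(ys[vapply(seq_len(B), function(b) sample.int(n), integer(n))],
                   n, B)
    r_null <- drop(crossprod(xs, perm)) / (n - 1)
    p_perm <- mean(abs(r_null) >= abs(pc$r) - 1e-12)
    se <- sqrt(max(pc$p * (1 - pc$p), 1 / B) / B)
    expect_lt(abs(pc$p - p_perm), 4 * se + 2 / B)
  }
})

test_that("DCP screen selects pairs by correlation difference and Fisher z", {
  # same pattern duplicated in both states: delta exactly 0
  set.seed(5)
  x <- rnorm(8); y <- 0.7 * x + rnorm(8, sd = 0.3)
  prot <- cohort_matrix(matrix(c(x, x), 16, 1, dimnames = list(sprintf("S%02d", 1:16), "K")),
                        rep(c(1L, 2L), each = 8), "protein")
  phos <- cohort_matrix(matrix(c(y, y), 16, 1, dimnames = list(sprintf("S%02d", 1:16), "G_S1")),
                        rep(c(1L, 2L), each = 8), "phosphosite")
  res <- dcp_screen(prot, phos, data.frame("K", "G_S1"),
                    min_abs_delta = 1e-6, alpha_level = 1)
  expect_equal(res$delta, 0)
  expect_false(res$selected)

  # construct r1 = +0.95, r2 = -0.95 exactly by orthogonalization
  make_cor <- function(r, n, seed) {
    set.seed(seed)
    x <- scale(rnorm(n))[, 1]
    e <- rnorm(n)
    e <- scale(residuals(lm(e ~ x)))[, 1]
    list(x = x, y = r * x + sqrt(1 - r^2) * e)
  }
  a <- make_cor(0.95, 15, 1)
  b <- make_cor(-0.95, 15, 2)
  prot2 <- cohort_matrix(matrix(c(a$x, b$x), 30, 1,
                                dimnames = list(sprintf("S%02d", 1:30), "K")),
                         rep(c(1L, 2L), each = 15), "protein")
  phos2 <- cohort_matrix(matrix(c(a$y, b$y), 30, 1,
                                dimnames = list(sprintf("S%02d", 1:30), "G_S1")),
                         rep(c(1L, 2L), each = 15), "phosphosite")
  res2 <- dcp_screen(prot2, phos2, data.frame("K", "G_S1"),
                     min_abs_delta = 1.0, alpha_level = 0.05)
  expect_equal(res2$r_state1, 0.95, tolerance = 1e-10)
  expect_equal(res2$r_state2, -0.95, tolerance = 1e-10)
  expect_equal(res2$delta, 1.9, tolerance = 1e-10)
  expect_true(res2$selected)

  # vacuous thresholds select every non-degenerate pair
  co <- random_cohort(n = 20, seed = 9)
  e <- build_edges(co$relations, co$protein, co$phosphosite)
  res3 <- dcp_screen(co$protein, co$phosphosite, e,
                     min_abs_delta = 0, alpha_level = 1)
  expect_true(all(res3$selected))

  # degenerate column: warned, reported unselected
  protd <- cohort_matrix(matrix(c(rep(1, 8), rnorm(8)), 16, 1,
                                dimnames = list(sprintf("S%02d", 1:16), "K")),
                         rep(c(1L, 2L), each = 8), "protein")
  expect_warning(res4 <- dcp_screen(protd, phos, data.frame("K", "G_S1"),
                                    min_abs_delta = 0, alpha_level = 1))
  expect_false(res4$selected)
  expect_true(is.na(res4$r_state1))

  # too few samples per state for Fisher z
  small <- random_cohort(n = 6, seed = 2)
  expect_error(dcp_screen(small$protein, small$phosphosite, NULL),
               class = "DegenerateStateError")
})
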