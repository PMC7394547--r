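# Permutation machinery, cluster correction, effect sizes, contingency and
# threshold arithmetic.

test_that("paired permutation t-test enumerates exhaustively on small n", {
  r <- permutation_t_paired(c(2, 1, -1), n_perm = 10000, seed = 1)
  expect_true(r$exhaustive)
  expect_identical(r$n_permutations, 8)
  expect_within(r$observed_stat, 0.7559, 1e-3)
  expect_equal(r$p_value, 0.75, tolerance = 1e-12)
  expect_error(permutation_t_paired(rep(1, 5), rep(0, 5)), "variance")
  expect_error(permutation_t_paired(c(1, 2)), "at least 3")
})

test_that("exhaustive and Monte-Carlo permutation p-values agree", {
  set.seed(2)
  for (i in 1:5) {
    d <- rnorm(10, mean = 0.4)
    ex <- permutation_t_paired(d, n_perm = 2000)          # 2^10 = 1024 <= 2000
    mc <- permutation_t_paired(d, n_perm = 999, seed = i) # forced Monte-Carlo
    expect_true(ex$exhaustive); expect_false(mc$exhaustive)
    tol <- 3 * sqrt(ex$p_value * (1 - ex$p_value) / 999) + 2 / 999
    expect_within(mc$p_value, ex$p_value, tol)
  }
})

test_that("a large paired shift drives p to the resolution floor", {
  set.seed(3)
  x <- rnorm(20) + 2; y <- rnorm(20)
  r <- permutation_t_paired(x, y, n_perm = 999, seed = 4)
  expect_equal(r$p_value, 1 / 1000, tolerance = 1e-12)
  expect_gt(r$effect_size_d, 1)
})

test_that("repeated-measures permutation ANOVA handles null and structured data", {
  # identical condition columns: F = 0, every permutation ties or exceeds
  d0 <- matrix(rnorm(8), 8, 3)
  d0[, 2] <- d0[, 1]; d0[, 3] <- d0[, 1]
  r0 <- permutation_rm_anova(d0, n_perm = 200, seed = 5)
  expect_equal(r0$observed_stat, 0, tolerance = 1e-9)
  expect_gt(r0$p_value, 0.99)
  # compound-symmetric covariance (forced empirically): GG epsilon = 1
  sigma <- diag(4) * 0.7 + 0.3
  dcs <- MASS::mvrnorm(12, rep(0, 4), sigma, empirical = TRUE)
  rcs <- permutation_rm_anova(dcs, n_perm = 100, seed = 6)
  expect_within(rcs$gg_epsilon, 1, 1e-9)
  expect_equal(rcs$df_corrected[1], 3, tolerance = 1e-9)
  # a real condition effect is detected
  de <- matrix(rnorm(30), 10, 3) + matrix(rep(c(0, 1, 2), each = 10), 10)
  re <- permutation_rm_anova(de, n_perm = 500, seed = 7)
  expect_lt(re$p_value, 0.01)
  expect_error(permutation_rm_anova(matrix(1:6, 3, 2)), "3 conditions")
  dm <- matrix(rnorm(12), 4, 3); dm[1, 1] <- NA
  expect_error(permutation_rm_anova(dm), "missing")
})

test_that("channel cluster permutation finds global effects and nothing under null", {
  adj <- adjacency_from_layout(montage25())
  n <- 10
  set.seed(8)
  base <- matrix(rnorm(n * 25), n, 25)
  # exact per-channel null: condition difference identically zero mean with
  # sub-threshold t everywhere (constant tiny alternating pattern)
  d0 <- matrix(rnorm(n * 25, sd = 1), n, 25)
  d0 <- sweep(d0, 2, colMeans(d0))               # per-channel mean 0 -> t = 0
  r0 <- cluster_permutation_channels(base + d0, base, adj, n_perm = 100,
                                     seed = 9)
  expect_identical(nrow(r0$clusters), 0L)
  # global shift (with subject-level noise): a single suprathreshold cluster
  # spanning all 25 channels
  eff_noise <- matrix(rnorm(n * 25, sd = 0.5), n, 25)
  r1 <- cluster_permutation_channels(base + 0.8 + eff_noise, base, adj,
                                     n_perm = 500, seed = 10)
  expect_identical(max(r1$clusters$size), 25L)
  expect_lt(min(r1$clusters$p_corrected), 0.02)
  # corrected p decreases monotonically with injected effect size (within
  # the noise-dominated regime where the sign-flip null is well behaved)
  ps <- sapply(c(0.15, 0.35, 0.6), function(es) {
    r <- cluster_permutation_channels(base + es + eff_noise, base, adj,
                                      n_perm = 300, seed = 11)
    if (nrow(r$clusters)) min(r$clusters$p_corrected) else 1
  })
  expect_true(all(diff(ps) <= 0))
  expect_error(cluster_permutation_channels(base, base, adj * 0), "empty")
})

test_that("Cohen's d follows both conventions and affine invariance", {
  expect_equal(as.numeric(cohens_d(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_within(as.numeric(cohens_d(c(2, 4), c(1, 3))), 0.7071, 1e-4)
  x <- rnorm(20); y <- rnorm(20)
  d1 <- as.numeric(cohens_d(x, y))
  d2 <- as.numeric(cohens_d(3 * x + 5, 3 * y + 5))
  expect_within(d2, d1, 1e-10)
  dp <- cohens_d(x, y, mode = "paired_diff")
  expect_identical(attr(dp, "mode"), "paired_diff")
  expect_within(as.numeric(dp), mean(x - y) / sd(x - y), 1e-12)
})

test_that("Yates-corrected chi-squared reproduces the published contingency values", {
  # regional electrode-count tables: medial vs lateral prefrontal and temporal
  t1 <- matrix(c(24, 15, 4, 58), 2)
  r1 <- chi2_2x2_yates(t1)
  expect_within(r1$statistic, 33.56, 0.02)
  expect_lt(r1$p_value, 1e-4)
  t2 <- matrix(c(33, 13, 15, 66), 2)
  expect_within(chi2_2x2_yates(t2)$statistic, 33.12, 0.02)
  # independent cross-check against the closed-form corrected statistic
  hand <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((abs(tab - e) - 0.5)^2 / e)
  }
  expect_within(r1$statistic, hand(t1), 1e-9)
  # proportional table: zero uncorrected statistic, corrected stays >= 0
  tp <- matrix(c(10, 20, 30, 60), 2)
  rp <- chi2_2x2_yates(tp)
  expect_equal(rp$statistic_uncorrected, 0, tolerance = 1e-12)
  expect_gte(rp$statistic, 0)
  expect_error(chi2_2x2_yates(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("continuity correction never exceeds the uncorrected statistic", {
  set.seed(12)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    r <- chi2_2x2_yates(tab)
    expect_lte(r$statistic, r$statistic_uncorrected + 1e-12)
  }
})

test_that("threshold arithmetic matches the published values", {
  expect_equal(r_to_t(0, 18), 0)
  expect_within(r_to_t(0.5, 18), 2.309, 1e-3)
  expect_equal(r_to_t(-0.5, 18), -r_to_t(0.5, 18))
  expect_error(r_to_t(1, 10), "below 1")
  expect_within(bonferroni_alpha(0.05, 19), 0.00263, 1e-4)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 25), 4e-4)
  expect_within(z_to_p_two_tailed(1.96), 0.05, 1e-3)
  expect_equal(z_to_p_two_tailed(0), 1)
  expect_within(z_to_p_two_tailed(2.576), 0.01, 1e-4)
  expect_error(z_to_p_two_tailed(Inf), "finite")
})
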