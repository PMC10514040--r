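test_that("Welch t behaves at its boundary cases and matches the formula", {
  a <- c(1, 2, 3, 4)
  same <- welch_t(a, a)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "degenerate")
  # equal variance and equal n: Welch equals pooled t exactly
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10)
  pooled <- stats::t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(welch_t(x, y)$t, unname(pooled), tolerance = 1e-12)
  # seeded samples against the textbook formula
  set.seed(2)
  x <- rnorm(8, 1, 2); y <- rnorm(15, 0, 0.5)
  w <- welch_t(x, y); o <- oracle_welch_t(x, y)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
})

test_that("summary-statistics ANOVA matches the demographics worked examples", {
  caps <- anova_f_from_summary(list(mean = 14.92, sd = 3.58, n = 14),
                               list(mean = 2.93, sd = 2.25, n = 29))
  expect_equal(caps$F, 180.45, tolerance = 0.001)  # printed as 180.45
  expect_equal(caps$df2, 41)   # 14 + 29 - 2
  expect_lt(caps$p, 0.001)
  age <- anova_f_from_summary(list(mean = 20.42, sd = 2.53, n = 14),
                              list(mean = 25.37, sd = 10.04, n = 29))
  expect_equal(age$F, 3.26, tolerance = 0.01)
  expect_equal(anova_f_from_summary(list(mean = 5, sd = 1, n = 10),
                                    list(mean = 5, sd = 2, n = 12))$F, 0)
  expect_error(anova_f_from_summary(list(mean = 1, sd = 1, n = 2),
                                    list(mean = 2, sd = 1, n = 1)))
})

test_that("2x2 chi-square matches the sex-ratio worked example and closed forms", {
  sex <- chi_square_2x2(matrix(c(7, 8, 7, 21), 2))
  expect_equal(sex$chi2, 2.088, tolerance = 0.001)
  expect_equal(sex$df, 1)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(chi_square_2x2(matrix(c(20, 0, 0, 20), 2))$chi2, 40)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "marginal")
})

test_that("KS normality screen calibrates on normal and rejects uniform", {
  set.seed(5)
  keep <- vapply(1:200, function(i)
    ks_normality(rnorm(500))$p > 0.05, logical(1))
  expect_gte(mean(keep), 0.9)
  # consistency against a flat alternative
  set.seed(6)
  rej <- vapply(1:20, function(i)
    ks_normality(runif(500))$p < 0.05, logical(1))
  expect_gte(mean(rej), 0.95)
  expect_error(ks_normality(rep(2, 10)), "variance")
  expect_error(ks_normality(c(1, 2)), "length")
})

test_that("BH correction matches the step-up oracle", {
  one <- fdr_bh(0.01, 0.05)
  expect_true(one$significant)
  flat <- fdr_bh(rep(0.5, 100), 0.05)
  expect_false(any(flat$significant))
  set.seed(9)
  p <- c(runif(80), runif(20, 0, 1e-3))
  got <- fdr_bh(p, 0.05)
  expect_equal(got$significant, oracle_fdr_mask(p, 0.05))
  expect_true(all(got$q_values >= p - 1e-15))
  empty <- fdr_bh(numeric(0))
  expect_length(empty$q_values, 0)
})

test_that("network comparisons report HS-minus-LS t with label-flip symmetry", {
  set.seed(12)
  hs <- matrix(rnorm(5 * 6), 5, dimnames = list(NULL, paste0("e", 1:6)))
  ls <- matrix(rnorm(9 * 6, 0.5), 9, dimnames = list(NULL, paste0("e", 1:6)))
  cmp <- compare_networks(hs, ls, level = "node_metric")
  expect_named(cmp, c("feature", "mean_hs", "mean_ls", "t", "df", "p",
                      "q", "significant", "direction"))
  flipped <- compare_networks(ls, hs, level = "node_metric")
  expect_all_equal(cmp$t, -flipped$t, tol = 1e-12)
  expect_all_equal(cmp$p, flipped$p, tol = 1e-12)
  # LS systematically higher -> negative t
  expect_true(all(cmp$t < 0 | cmp$p > 0.05))
})

test_that("exchangeable groups stay null-calibrated", {
  set.seed(13)
  n_feat <- 150
  raw_rate <- replicate(20, {
    x <- matrix(rnorm(12 * n_feat), 12)
    colnames(x) <- paste0("f", seq_len(n_feat))
    cmp <- compare_networks(x[1:5, ], x[6:12, ], level = "edge")
    c(fdr = sum(cmp$significant), raw = mean(cmp$p < 0.05))
  })
  expect_lte(mean(raw_rate["fdr", ] > 0), 0.2)   # FDR: rarely any hit
  expect_lt(abs(mean(raw_rate["raw", ]) - 0.05), 0.025)
})
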