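test_that("diameter-thickness regression recovers exact and hand-worked fits", {
  d <- seq(0.5, 3, by = 0.5)
  r <- fit_diameter_thickness(d, 0.2 * d + 0.13)
  expect_equal(r$slope, 0.2)
  expect_equal(r$intercept, 0.13)
  expect_equal(r$r_squared, 1)

  # hand-computed OLS on 5 points: slope = Sxy/Sxx, R^2 = Sxy^2/(Sxx*Syy)
  x <- 1:5; y <- c(0.3, 0.5, 0.8, 0.9, 1.2)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  r2 <- fit_diameter_thickness(x, y)
  expect_equal(r2$slope, sxy / sxx)
  expect_equal(r2$intercept, mean(y) - sxy / sxx * mean(x))
  expect_equal(r2$r_squared, sxy^2 / (sxx * syy))

  expect_error(fit_diameter_thickness(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(fit_diameter_thickness(1:2, 1:2), "at least 3")
  # constant y on varying x: R^2 = 0 when y is noisy-constant
  expect_equal(fit_diameter_thickness(1:10, rep(2, 10))$r_squared, 0)
})

test_that("R-squared is invariant under affine rescaling of both variables", {
  set.seed(3)
  x <- runif(30, 0.3, 2); y <- 0.2 * x + 0.13 + rnorm(30, 0, 0.05)
  r1 <- fit_diameter_thickness(x, y)$r_squared
  r2 <- fit_diameter_thickness(1000 * x - 7, -2 * y + 11)$r_squared
  expect_equal(r1, r2)
})

test_that("classic Levene matches the mean-centred reference implementation", {
  expect_true(requireNamespace("car", quietly = TRUE))
  set.seed(21)
  a <- rnorm(25, 0, 1); b <- rnorm(30, 0, 3)
  lv <- levene_test(a, b)
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(25, 30))), center = mean)
  expect_equal(lv$statistic, ref$`F value`[1])
  expect_equal(lv$p, ref$`Pr(>F)`[1])
  expect_lt(lv$p, 0.01)

  ident <- levene_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  expect_error(levene_test(1, c(1, 2)), "n >= 2")
})

test_that("unpaired t-test matches hand-computed pooled-variance values", {
  tt <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6), equal_var = TRUE)
  expect_equal(tt$statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$p, 0.0214, tolerance = 1e-2)
  expect_equal(tt$df, 4)

  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  degen <- unpaired_t_test(c(2, 2), c(2, 2))
  expect_equal(degen$statistic, 0); expect_equal(degen$p, 1)
  # symmetry: swapping groups negates t, preserves p
  a <- rnorm(10); b <- rnorm(12, 1)
  t1 <- unpaired_t_test(a, b); t2 <- unpaired_t_test(b, a)
  expect_equal(t1$statistic, -t2$statistic)
  expect_equal(t1$p, t2$p)
})

test_that("the Levene gate selects Student vs Welch", {
  set.seed(5)
  a <- rnorm(40, 0, 1); b <- rnorm(40, 0, 4)
  row <- compare_two_groups(a, b)
  expect_false(row$equal_var)              # variances clearly unequal -> Welch
  c2 <- compare_two_groups(rnorm(40), rnorm(40))
  expect_true(c2$equal_var)
})

test_that("repeated-measures ANOVA matches a hand-worked decomposition", {
  # 5 subjects x 3 conditions
  m <- matrix(c(30, 28, 16, 34, 32,
                25, 29, 14, 31, 30,
                20, 24, 10, 28, 25), nrow = 5)
  colnames(m) <- c("c1", "c2", "c3")
  res <- rm_anova_tukey(m)
  # hand decomposition: SS_cond (between conditions), SS_subj, SS_err
  gm <- mean(m)
  ss_cond <- 5 * sum((colMeans(m) - gm)^2)
  ss_subj <- 3 * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_hand <- (ss_cond / 2) / (ss_err / 8)
  expect_equal(res$anova$statistic, f_hand)
  expect_equal(res$anova$df1, 2); expect_equal(res$anova$df2, 8)
  expect_equal(res$anova$p, stats::pf(f_hand, 2, 8, lower.tail = FALSE))
  expect_equal(nrow(res$tukey), 3)
  # Tukey adjusted p via the studentized range on the error mean square
  mse <- ss_err / 8
  q12 <- abs(mean(m[, 1]) - mean(m[, 2])) / sqrt(mse / 5)
  expect_equal(res$tukey$p_adj[res$tukey$pair == "c2-c1"],
               stats::ptukey(q12, 3, 8, lower.tail = FALSE))
})

test_that("repeated-measures ANOVA guards degenerate and incomplete input", {
  flat <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)
  res <- rm_anova_tukey(flat)                 # identical conditions
  expect_equal(res$anova$statistic, 0)
  expect_equal(res$anova$p, 1)
  expect_true(all(res$tukey$p_adj == 1))
  bad <- matrix(c(1, 2, 3, NA, 5, 6), nrow = 3)
  expect_error(rm_anova_tukey(bad), "incomplete")
  expect_error(rm_anova_tukey(matrix(1:4, 2)), "3 subjects")
  expect_error(rm_anova_tukey(matrix(1:4, 4)), "2 conditions")
})
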