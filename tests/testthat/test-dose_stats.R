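test_that("FI binning uses half-open bins with inclusive lower edges", {
  rec <- data.frame(fi = c(1.99, 2.0, 3.999, 4.0, 7.999, 8.0, 25))
  b <- bin_by_fi(rec)
  expect_equal(as.character(b$fi_bin),
               c("FI<2", "2<=FI<4", "2<=FI<4", "4<=FI<8", "4<=FI<8",
                 "FI>=8", "FI>=8"))
  expect_equal(nrow(bin_by_fi(rec[0, , drop = FALSE])), 0)
  expect_error(bin_by_fi(rec, edges = c(4, 2)), "increasing")
})

test_that("expression normalization maps the control mean to 1", {
  rec <- data.frame(fi = c(0.5, 0.8, 3), expression_ratio = c(1, 1, 0.5))
  out <- normalize_expression(rec)
  expect_equal(out$relative_expression, c(1, 1, 0.5))

  rec2 <- data.frame(fi = c(0.5, 3), expression_ratio = c(2, 1))
  expect_equal(normalize_expression(rec2)$relative_expression, c(1, 0.5))

  allc <- data.frame(fi = runif(10, 0, 0.9),
                     expression_ratio = runif(10, 0.5, 2))
  expect_equal(mean(normalize_expression(allc)$relative_expression), 1)

  expect_error(normalize_expression(data.frame(fi = 5,
                                               expression_ratio = 1)),
               "control")
})

test_that("Spearman correlation handles monotone data and ties", {
  x <- 1:8
  expect_equal(spearman_corr(x, -2 * x + 3)$rho, -1)
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_error(spearman_corr(x, rep(1, 8)), "constant")
  # invariance under strictly monotone transforms
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20)
  r0 <- spearman_corr(a, b)$rho
  expect_equal(spearman_corr(exp(a), b)$rho, r0)
  expect_equal(spearman_corr(a, b^3)$rho, r0)
  # agrees with the standard rank-correlation estimate
  expect_equal(spearman_corr(a, b)$rho,
               unname(cor(a, b, method = "spearman")))
})

test_that("Student's t test wrapper matches stats::t.test and conventions", {
  set.seed(3)
  a <- rnorm(10); b <- rnorm(12, 1)
  ours <- t_test_two_sided(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  # swap symmetry
  sw <- t_test_two_sided(b, a)
  expect_equal(sw$t, -ours$t)
  expect_equal(sw$p, ours$p)
  # equal constant groups: p = 1; separated constants: p -> 0
  expect_equal(t_test_two_sided(c(1, 1), c(1, 1))$p, 1)
  expect_equal(t_test_two_sided(c(0, 0), c(1, 1))$p, 0)
  jit <- c(1, 1, 1, 1) + c(0, 1e-9, 0, -1e-9)
  expect_lt(t_test_two_sided(c(0, 0, 0, 0) + c(0, 1e-9, 0, -1e-9), jit)$p,
            1e-4)
})

test_that("Bonferroni pairwise comparisons use the comparison-count multiplier", {
  set.seed(4)
  vals <- c(rnorm(10), rnorm(10), rnorm(10))
  grp <- rep(c("a", "b", "c"), each = 10)
  out <- bonferroni_pairwise(vals, grp)
  expect_equal(nrow(out), 3)
  expect_equal(out$p_adjusted, pmin(1, out$p_raw * 3))
  expect_true(all(out$p_adjusted >= out$p_raw))
  expect_true(all(out$p_adjusted <= 1))

  # identical groups: adjusted p = 1
  same <- bonferroni_pairwise(rep(c(1, 2, 3), 3), rep(c("a", "b"),
                                                      length.out = 9))
  expect_true(all(same$p_adjusted <= 1))

  # groups shifted by 2 SD at n = 50: all significant
  shifted <- c(rnorm(50, 0), rnorm(50, 2), rnorm(50, 4))
  g3 <- rep(c("lo", "mid", "hi"), each = 50)
  res <- bonferroni_pairwise(shifted, g3)
  expect_true(all(res$p_adjusted < 0.01))

  w <- testthat::capture_warnings(
    out1 <- bonferroni_pairwise(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")))
  expect_match(w, "skipping", all = TRUE)
  expect_equal(nrow(out1), 1)   # only a vs b testable, multiplier 1
  expect_equal(out1$p_adjusted, out1$p_raw)
})

test_that("2x2 chi-square follows the closed-form Pearson statistic", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- chi_square_2x2(even)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  diag5 <- matrix(c(5, 0, 0, 5), 2)
  rd <- chi_square_2x2(diag5)
  expect_equal(rd$chi2, 10)
  expect_equal(rd$p, pchisq(10, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(rd$p, 1.565402e-3, tolerance = 1e-4)

  # invariance under transposition and row/col swaps
  tb <- matrix(c(7, 3, 2, 9), 2)
  r0 <- chi_square_2x2(tb)
  expect_equal(chi_square_2x2(t(tb))$chi2, r0$chi2)
  expect_equal(chi_square_2x2(tb[2:1, ])$chi2, r0$chi2)
  expect_equal(chi_square_2x2(tb[, 2:1])$chi2, r0$chi2)

  # Yates correction reduces the statistic
  expect_lt(chi_square_2x2(tb, yates = TRUE)$chi2, r0$chi2)

  expect_error(chi_square_2x2(matrix(c(1, 0, 2, 0), 2)), "margins")
  expect_error(chi_square_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("simulated cohorts show the negative FI-expression dose response", {
  co <- simulate_morphant_cohort(cohort_params(n = 300, seed = 99))
  co <- normalize_expression(co)
  sp <- spearman_corr(co$fi, co$relative_expression)
  expect_lt(sp$rho, 0)
  expect_lt(sp$p, 0.01)
  # FI differs across phenotype severity groups
  res <- bonferroni_pairwise(co$fi, co$phenotype)
  expect_true(any(res$significant))
})
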