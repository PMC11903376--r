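test_that("two-proportion z reproduces the registry p-values at 3 dp", {
  # printed contingency tables from the cohort report
  cases <- list(
    list(k1 = 2, n1 = 9, k2 = 13, n2 = 16, p = 0.002),   # prior ablation
    list(k1 = 2, n1 = 9, k2 = 12, n2 = 16, p = 0.005),   # cardioversion
    list(k1 = 7, n1 = 9, k2 = 5, n2 = 16, p = 0.013),    # per protocol
    list(k1 = 11, n1 = 13, k2 = 2, n2 = 8, p = 0.003),   # FFAF de novo/redo
    list(k1 = 9, n1 = 10, k2 = 5, n2 = 11, p = 0.015),   # FFAF EGFC split
    list(k1 = 3, n1 = 9, k2 = 1, n2 = 16, p = 0.038)     # Type I enrichment
  )
  for (cc in cases) {
    res <- two_prop_z(cc$k1, cc$n1, cc$k2, cc$n2)
    expect_equal(round(res$p_one_tailed, 3), cc$p)
  }
})

test_that("two-proportion z is symmetric and antisymmetric as expected", {
  expect_equal(two_prop_z(5, 10, 5, 10)$statistic, 0)
  expect_equal(two_prop_z(5, 10, 5, 10)$p_one_tailed, 0.5)
  a <- two_prop_z(9, 10, 5, 11)
  b <- two_prop_z(5, 11, 9, 10)
  expect_equal(b$statistic, -a$statistic)
  expect_equal(b$p_one_tailed, a$p_one_tailed)
  expect_error(two_prop_z(1, 0, 1, 2))
  expect_error(two_prop_z(3, 2, 1, 2))
})

test_that("summary t-test reproduces the sources-per-patient p-value", {
  res <- t_test_from_summary(0.9, 1.2, 9, 2.2, 1.3, 16)
  expect_equal(round(res$p_one_tailed, 3), 0.011)
  expect_equal(res$df, 23)
})

test_that("summary t-test handles equal means and degenerate variance", {
  expect_equal(t_test_from_summary(1, 2, 5, 1, 3, 7)$statistic, 0)
  expect_equal(t_test_from_summary(1, 2, 5, 1, 3, 7)$p_one_tailed, 0.5)
  z <- t_test_from_summary(1, 0, 5, 1, 0, 5)
  expect_equal(z$p_one_tailed, 0.5)
  d <- t_test_from_summary(2, 0, 5, 1, 0, 5)
  expect_equal(d$p_one_tailed, 0)
  expect_true(d$degenerate)
})

test_that("summary t-test agrees with a resampling oracle", {
  # simulate group data at the stated moments and compare the analytic
  # one-tailed p with the Monte-Carlo rejection behavior of t.test
  set.seed(42)
  m1 <- 0.5; s1 <- 1; n1 <- 12; m2 <- 1.2; s2 <- 1.1; n2 <- 15
  analytic <- t_test_from_summary(m1, s1, n1, m2, s2, n2)
  ps <- replicate(400, {
    x <- stats::rnorm(n1, m1, s1); y <- stats::rnorm(n2, m2, s2)
    # recompute from the sample's own summary stats: must agree with
    # t.test's pooled-variance one-sided p on the same data
    a <- t_test_from_summary(mean(x), sd(x), n1, mean(y), sd(y), n2)
    b <- stats::t.test(x, y, var.equal = TRUE,
                       alternative = if (mean(x) > mean(y)) "greater" else "less")
    abs(a$p_one_tailed - b$p.value)
  })
  expect_lt(max(ps), 1e-10)
  expect_gt(analytic$p_one_tailed, 0)
})

test_that("linear regression matches the closed-form normal equations", {
  set.seed(7)
  x <- stats::rnorm(40); y <- 1.5 * x - 2 + stats::rnorm(40, sd = 0.3)
  res <- linreg(x, y)
  # independent solve
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(res$slope, slope)
  expect_equal(res$intercept, intercept)
  expect_equal(res$r_squared, res$r^2)
  # exact line
  ex <- linreg(1:10, 2 * (1:10) + 1)
  expect_equal(ex$r, 1)
  expect_lt(ex$F_p, 1e-12)
  # null: no relationship
  set.seed(11)
  nres <- linreg(stats::rnorm(100), stats::rnorm(100))
  expect_lt(abs(nres$r), 0.3)
  expect_gt(nres$F_p, 0.05)
  expect_error(linreg(rep(1, 5), 1:5))
})

test_that("registry report recomputes every bundled comparison", {
  rep <- registry_report()
  expect_gte(nrow(rep), 10)
  core <- rep[rep$core, ]
  expect_equal(nrow(core), 7)
  expect_equal(round(core$p, 3), core$printed_p)
  # the non-core de novo PAF comparison is the known 3-dp mismatch
  odd <- rep[rep$name == "ffaf_paf_denovo_vs_redo", ]
  expect_equal(round(odd$p, 3), 0.018)
  expect_equal(odd$printed_p, 0.017)
  tsv <- tempfile(fileext = ".tsv")
  registry_report(tsv = tsv)
  expect_true(file.exists(tsv))
})
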