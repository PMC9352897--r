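# Agreement statistics: Pearson with non-correlation test, Lin's
# concordance coefficient, Bland-Altman, normality screen, stratified
# comparisons.

test_that("Pearson handles the perfect and degenerate cases", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_error(pearson_with_p(c(1, 2, 3), c(2, 2, 2)),
               class = "ctbca_degenerate_sample_error")
  expect_error(pearson_with_p(c(1, 2), c(3, 4)),
               class = "ctbca_degenerate_sample_error")
})

test_that("Pearson r and p match the standard product-moment test", {
  set.seed(14)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40, sd = 0.8)
  got <- pearson_with_p(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value)
})

test_that("Pearson is invariant under positive affine maps", {
  set.seed(15)
  x <- rnorm(30); y <- rnorm(30)
  base <- pearson_with_p(x, y)$r
  expect_equal(pearson_with_p(3 * x + 7, y)$r, base)
  expect_equal(pearson_with_p(x, 0.2 * y - 4)$r, base)
  expect_equal(pearson_with_p(-2 * x, y)$r, -base)
})

test_that("Lin's coefficient matches hand-evaluated worked examples", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3))$ccc, 1)
  # equal means, cov = -var: rho_c = -1
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1))$ccc, -1)
  # shifted by 1: 2 * (2/3) / (2/3 + 2/3 + 1) = 4/7, while r = 1
  res <- lin_ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$ccc, 4 / 7)
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 3, 4))$r, 1)
  expect_error(lin_ccc(c(1, 2, 3), c(2, 2, 2)),
               class = "ctbca_degenerate_sample_error")
})

test_that("|ccc| <= |r|, with equality under equal means and variances", {
  set.seed(16)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sample(-5:5, 1), runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(n, sample(-5:5, 1), runif(1, 0.5, 3))
    ccc <- lin_ccc(x, y, ci_level = NULL)$ccc
    r <- pearson_with_p(x, y)$r
    expect_lte(abs(ccc), abs(r) + 1e-12)
    # permutation of x has identical mean and variance: ccc collapses to r
    yp <- sample(x)
    if (var(yp) > 0 && cor(x, yp) != 0) {
      expect_equal(lin_ccc(x, yp, ci_level = NULL)$ccc,
                   pearson_with_p(x, yp)$r)
    }
  }
})

test_that("Lin CI contains the estimate and tightens with n", {
  set.seed(17)
  x <- rnorm(200, 30, 5); y <- x + rnorm(200, 1, 2)
  res <- lin_ccc(x, y)
  expect_true(res$ci[1] <= res$ccc && res$ccc <= res$ci[2])
  small <- lin_ccc(x[1:20], y[1:20])
  expect_gt(diff(small$ci), diff(res$ci))
})

test_that("Lin CI covers the population coefficient at roughly the nominal rate", {
  # population: x ~ N(0,1), y = x + e, e ~ N(mu_d, sd_e^2)
  mu_d <- 0.5; sd_e <- 0.8
  pop_ccc <- 2 * 1 / (1 + (1 + sd_e^2) + mu_d^2)
  set.seed(18)
  hits <- vapply(1:400, function(i) {
    x <- rnorm(50)
    y <- x + rnorm(50, mu_d, sd_e)
    ci <- lin_ccc(x, y)$ci
    ci[1] <= pop_ccc && pop_ccc <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("Bland-Altman constant-offset and identity cases", {
  y <- c(10, 20, 30, 40, 50)
  ba <- bland_altman(y + 5, y)
  expect_equal(ba$mean_diff, 5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(5, 5))
  expect_equal(bland_altman(y, y)$mean_diff, 0)
  expect_error(bland_altman(c(1, 2), c(1, 2)),
               class = "ctbca_degenerate_sample_error")
})

test_that("Bland-Altman interval structure holds", {
  set.seed(19)
  x <- rnorm(60, 35, 8); y <- x + rnorm(60, -2, 1.5)
  ba <- bland_altman(x, y)
  expect_true(ba$loa_low <= ba$mean_diff && ba$mean_diff <= ba$loa_high)
  expect_true(ba$ci_mean[1] <= ba$mean_diff && ba$mean_diff <= ba$ci_mean[2])
  expect_true(ba$ci_loa_low[1] <= ba$loa_low && ba$loa_low <= ba$ci_loa_low[2])
  expect_true(ba$ci_loa_high[1] <= ba$loa_high &&
                ba$loa_high <= ba$ci_loa_high[2])
  expect_equal(ba$loa_high - ba$mean_diff, 1.96 * ba$sd_diff)
  expect_equal(nrow(ba$points), 60)
})

test_that("Bland-Altman is antisymmetric in the method order", {
  set.seed(20)
  x <- rnorm(40, 30, 5); y <- x + rnorm(40, 3, 1)
  ab <- bland_altman(x, y)
  ba <- bland_altman(y, x)
  expect_equal(ba$mean_diff, -ab$mean_diff)
  expect_equal(ba$loa_low, -ab$loa_high)
  expect_equal(ba$loa_high, -ab$loa_low)
  expect_equal(ba$sd_diff, ab$sd_diff)
})

test_that("normality screen behaves under null and lognormal alternative", {
  set.seed(22)
  gauss <- rnorm(500)
  expect_gt(shapiro_wilk(gauss)$p, 0.001)
  lnorm <- exp(rnorm(500))
  expect_lt(shapiro_wilk(lnorm)$p, 0.01)
  expect_error(shapiro_wilk(c(1, 1, 1)),
               class = "ctbca_degenerate_sample_error")
  expect_error(shapiro_wilk(rnorm(2)), class = "ctbca_unsupported_size_error")
  expect_error(shapiro_wilk(rnorm(5001)), class = "ctbca_unsupported_size_error")
})

test_that("compare_methods: zero-error cohort gives perfect agreement everywhere", {
  spec <- cohort_spec(
    n_subjects = 60,
    error_models = list(bfr_bca = method_error_model(),
                        bfr_dxa = method_error_model()),
    seed = 23
  )
  tab <- generate_cohort(spec)
  for (strat in c("none", "bmi", "sex")) {
    cmp <- compare_methods(tab, "bfr", c("bca", "dxa"), stratify = strat)
    for (s in cmp$strata) {
      expect_equal(s$agreement$r, 1)
      expect_equal(s$agreement$ccc, 1)
      expect_equal(s$bland_altman$mean_diff, 0)
    }
  }
})

test_that("compare_methods drops incomplete pairs per comparison", {
  tab <- generate_cohort(cohort_spec(n_subjects = 40, seed = 24,
                                     error_models = list(
                                       bfr_bca = method_error_model(),
                                       bfr_dxa = method_error_model(
                                         noise_sd = 1, p_missing = 0.3))))
  cmp <- compare_methods(tab, "bfr", c("bca", "dxa"))
  n_complete <- sum(!is.na(tab$bfr_bca) & !is.na(tab$bfr_dxa))
  expect_equal(cmp$strata$overall$agreement$n, n_complete)
  expect_equal(cmp$strata$overall$bland_altman$n, n_complete)
})

test_that("strata with fewer than 3 complete pairs are skipped with a warning", {
  tab <- generate_cohort(cohort_spec(n_subjects = 40,
                                     bmi_group_weights = c(19, 19, 2),
                                     allocation = "stratified_exact",
                                     error_models = list(
                                       bfr_bca = method_error_model(noise_sd = 1),
                                       bfr_dxa = method_error_model(noise_sd = 1)),
                                     seed = 25))
  expect_warning(
    cmp <- compare_methods(tab, "bfr", c("bca", "dxa"), stratify = "bmi"),
    "obese"
  )
  expect_false("obese" %in% names(cmp$strata))
  expect_true(all(c("overall", "healthy", "overweight") %in% names(cmp$strata)))
})

test_that("difference direction is first-listed minus second-listed", {
  tab <- generate_cohort(cohort_spec(
    n_subjects = 200,
    error_models = list(bfr_bca = method_error_model(),
                        bfr_dxa = method_error_model(bias_intercept = -5)),
    seed = 26))
  cmp <- compare_methods(tab, "bfr", c("bca", "dxa"))
  expect_gt(cmp$strata$overall$bland_altman$mean_diff, 4.5)
  rev_cmp <- compare_methods(tab, "bfr", c("dxa", "bca"))
  expect_lt(rev_cmp$strata$overall$bland_altman$mean_diff, -4.5)
})
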