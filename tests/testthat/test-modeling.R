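test_that("fit_ols recovers exact and noisy linear relations", {
  x <- c(1, 2, 3, 4, 7)
  f <- suppressWarnings(fit_ols(x, 2 * x + 1))  # lm warns on perfect fits
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-12)
  expect_equal(f$errors$abs_pe, 0, tolerance = 1e-12)

  set.seed(51)
  x2 <- runif(41, 50, 500)
  y2 <- x2 + rnorm(41, 0, 20)
  f2 <- fit_ols(x2, y2)
  se <- sqrt(sum(f2$residuals^2) / 39 / sum((x2 - mean(x2))^2))
  expect_lt(abs(f2$slope - 1), 3 * se)
  expect_error(fit_ols(rep(3, 10), rnorm(10)), "zero-variance")
  expect_error(fit_ols(1:2, 1:2), "at least 3")
})

test_that("fit_ols equals the closed-form normal equations", {
  set.seed(52)
  for (rep in 1:5) {
    x <- rnorm(20, 100, 30)
    y <- 0.07 * x + 3 + rnorm(20, 0, 2)
    f <- fit_ols(x, y)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(f$slope, slope, tolerance = 1e-12)
    expect_equal(f$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  }
})

test_that("OLS diagnostics behave on reference cases", {
  set.seed(53)
  x <- runif(200, 0, 10)
  y <- 2 * x + rnorm(200)
  d <- fit_ols(x, y)$diagnostics
  expect_lt(abs(d$durbin_watson - 2), 0.4)     # iid residuals: DW ~ 2
  expect_gt(d$breusch_pagan_p, 0.001)          # homoscedastic
  expect_lt(d$anova_f_p, 1e-4)                 # strong linear signal
  expect_identical(nrow(d$qq), 200L)
  # strongly autocorrelated residuals push DW toward 0
  e <- as.numeric(stats::filter(rnorm(200), 0.95, method = "recursive"))
  da <- fit_ols(x, 2 * x + e)$diagnostics
  expect_lt(da$durbin_watson, 1)
  # variance growing with x: BP should reject
  yh <- 2 * x + rnorm(200, 0, 0.2 + x)
  expect_lt(fit_ols(x, yh)$diagnostics$breusch_pagan_p, 0.01)
})

test_that("error metrics match hand computation", {
  expect_equal(abs_pred_error(c(10, 8), c(8, 10)), 2)
  expect_equal(abs_pred_error(c(12, 9, 15), c(10, 10, 12)), 2)
  expect_equal(abs_pred_error(1:5, 1:5), 0)
  expect_error(abs_pred_error(1:3, 1:4), "equal length")
  expect_equal(pct_pred_error(10, 8), 25)
  expect_equal(pct_pred_error(c(11, 9), c(10, 10)), 10)
  expect_equal(pct_pred_error(c(11, 9), c(10, 10), signed = TRUE), 0)
  expect_equal(pct_pred_error(1:4, 1:4), 0)
  expect_error(pct_pred_error(1, 0), "nonzero")
})

test_that("signed-rank test matches exact enumeration and stats oracle", {
  expect_equal(compare_paired_abs_errors(1:8, 1:8), 1)
  set.seed(54)
  a <- rnorm(20); b <- a + 10
  expect_lt(compare_paired_abs_errors(b, a), 0.001)
  # n = 8 shift within noise
  a8 <- rnorm(8); b8 <- a8 + rnorm(8, 0.1, 1)
  expect_gt(compare_paired_abs_errors(a8, b8), 0.05)
  # exact enumeration oracle over random small cases
  for (r in 1:20) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    d <- d[d != 0]
    if (length(d) < 5) next
    p_pkg <- compare_paired_abs_errors(d, rep(0, length(d)))
    expect_equal(p_pkg, wilcoxon_oracle(d), tolerance = 1e-10)
  }
  # agreement with stats::wilcox.test when ties are absent
  set.seed(55)
  for (r in 1:10) {
    a <- rnorm(12); b <- rnorm(12, 0.5)
    p_ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(compare_paired_abs_errors(a, b), p_ref, tolerance = 1e-10)
  }
})

test_that("LOOCV is deterministic, stateless, and near-zero on clean data", {
  set.seed(56)
  co <- make_cohort(cohort_spec(n = 15, seed = 56,
                                abs_pe = c(at_l3l4 = 1e-9, at_l4l5 = 1e-9,
                                           at_midthigh = 1e-9,
                                           lt_l3l4 = 1e-9, lt_l4l5 = 1e-9,
                                           lt_midthigh = 1e-9)))
  spec <- ols_model_spec("at_area_l4l5", "at_volume_L")
  expect_lt(loocv_mae(co, spec), 1e-6)
  co2 <- make_cohort(cohort_spec(seed = 57))
  m1 <- loocv_mae(co2, spec)
  m2 <- loocv_mae(co2, spec)
  expect_identical(m1, m2)
  # exactly n fits
  calls <- 0L
  counting <- list(
    fit = function(d) { calls <<- calls + 1L; spec$fit(d) },
    predict = spec$predict, target = spec$target)
  loocv_mae(co2, counting)
  expect_identical(calls, nrow(co2))
})

test_that("cohort validation catches schema and consistency violations", {
  co <- make_cohort(cohort_spec(seed = 58))
  expect_silent(validate_cohort(co))
  bad <- co; bad$at_mass_kg[3] <- bad$at_mass_kg[3] + 1
  expect_error(validate_cohort(bad), "0.92")
  bad2 <- co; bad2$weight_kg[1] <- bad2$weight_kg[1] + 5
  expect_error(validate_cohort(bad2), "weight")
  expect_error(validate_cohort(co[, -3]), "missing columns")
  bad3 <- co; bad3$at_area_l4l5[2] <- NA
  expect_error(validate_cohort(bad3), "at_area_l4l5")
})
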