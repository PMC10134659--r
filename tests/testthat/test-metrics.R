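test_that("AUC matches enumeration and trapezoidal integration", {
  # toy: 4 case-control pairs, 3 concordant -> 0.75
  expect_equal(auc_roc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  # perfectly separating scores
  expect_equal(auc_roc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  # rank form equals trapezoid on random instances, including ties
  for (seed in 1:6) {
    set.seed(seed)
    n <- 60
    y <- rbinom(n, 1, 0.3)
    if (var(y) == 0) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # heavy ties
    expect_equal(auc_roc(s, y), roc_trapezoid(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rbinom(100, 1, 0.4)
  s <- rnorm(100) + y
  ref <- as.numeric(suppressMessages(pROC::auc(y, s)))
  expect_equal(auc_roc(s, y), ref, tolerance = 1e-10)
})

test_that("uninformative scores give AUC near one half", {
  set.seed(11)
  y <- rbinom(4000, 1, 0.3)
  s <- rnorm(4000)
  expect_lt(abs(auc_roc(s, y) - 0.5), 0.04)
})

test_that("AUC input validation", {
  expect_error(auc_roc(c(1, 2), c(1, 0, 1)), "lengths")
  expect_error(auc_roc(c(1, 2), c(1, 1)), "both outcome classes")
  expect_error(auc_roc(c(1, NA), c(1, 0)), "finite")
})

test_that("model comparison reports delta AIC/AUC and the preferred model", {
  ds <- small_dataset(n = 300, seed = 17)
  fit1 <- fit_logistic(death ~ age, ds$cohort)
  fit2 <- fit_logistic(death ~ age + triage, ds$cohort)
  cmp <- compare_models(fit1, fit2)
  expect_equal(cmp$delta_aic, fit2$aic - fit1$aic, tolerance = 1e-12)
  expect_equal(cmp$auc_a, auc_roc(fit1$fitted, fit1$outcome))
  expect_equal(cmp$preferred, if (cmp$delta_aic < 0) "b" else "a")
  # identical fits: no preference
  cmp0 <- compare_models(fit1, fit1)
  expect_equal(cmp0$delta_aic, 0)
  expect_equal(cmp0$preferred, "neither")
  # different sample sizes refuse comparison
  fit3 <- fit_logistic(death ~ age, ds$cohort[1:200, ])
  expect_error(compare_models(fit1, fit3), "sample sizes")
})

test_that("residual Moran check validates its inputs and delegates", {
  ds <- small_dataset(n = 250, seed = 19)
  fit <- fit_logistic(death ~ age + sex, ds$cohort)
  expect_error(residual_moran_check(fit, ds$weights, residual_type = "junk"),
               "pearson, deviance, response")
  got <- residual_moran_check(fit, ds$weights, n_permutations = 99, seed = 2)
  # equals a direct Moran test on the Pearson residuals (one-sided default)
  direct <- global_morans_i(ds$weights,
                            as.numeric(residuals(fit$model, "pearson")),
                            n_permutations = 99, seed = 2,
                            alternative = "greater")
  expect_equal(got$statistic, direct$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, direct$p_value)
})
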