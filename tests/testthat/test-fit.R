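test_that("intercept-only fit matches the closed-form log-odds", {
  # 167 events in 1170 trials -> intercept ln(167/1003)
  d <- data.frame(death = rep(c(1L, 0L), c(167, 1003)))
  fit <- fit_logistic(death ~ 1, d)
  expect_equal(fit$terms$estimate, log(167 / 1003), tolerance = 1e-8)
  expect_equal(fit$n_events, 167)
})

test_that("a single binary covariate reproduces the 2x2 cross-product OR", {
  # triage table of the motivating registry: deaths 143 (levels 1&2) vs 24
  # (levels 3&4); survivors 666 vs 338
  d <- data.frame(
    death = rep(c(1L, 1L, 0L, 0L), c(143, 24, 666, 338)),
    triage = factor(rep(c("levels12", "levels34", "levels12", "levels34"),
                        c(143, 24, 666, 338)),
                    levels = c("levels12", "levels34"))
  )
  fit <- fit_logistic(death ~ triage, d)
  or_hand <- (24 * 666) / (143 * 338) # levels34 vs reference levels12
  row <- fit$terms[fit$terms$term == "triagelevels34", ]
  expect_equal(row$or, or_hand, tolerance = 1e-8)
  expect_equal(row$estimate, log(or_hand), tolerance = 1e-8)
  # intercept is the log-odds in the reference column
  expect_equal(fit$terms$estimate[1], log(143 / 666), tolerance = 1e-8)
  # Wald CI brackets the OR
  expect_lt(row$ci_low, row$or)
  expect_gt(row$ci_high, row$or)
  # AIC identity: 2k - 2 logLik
  expect_equal(fit$aic, 2 * 2 - 2 * fit$log_lik, tolerance = 1e-10)
})

test_that("fitted probabilities sum to the event count (score equation)", {
  ds <- small_dataset(n = 200, seed = 5)
  fit <- fit_logistic(death ~ age + sex + los, ds$cohort)
  expect_equal(sum(fit$fitted), fit$n_events, tolerance = 1e-6)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("degenerate and ill-posed designs are reported", {
  d <- data.frame(death = rep(0L, 20), xvar = rnorm(20))
  expect_error(fit_logistic(death ~ xvar, d), "no events")
  d$death <- 1L
  expect_error(fit_logistic(death ~ xvar, d), "non-events")
  # collinear design names the aliased column
  d2 <- data.frame(death = rbinom(40, 1, 0.5), a = rnorm(40))
  d2$b <- 2 * d2$a
  expect_error(fit_logistic(death ~ a + b, d2), "collinear.*b")
  # missing values must be handled upstream
  d3 <- data.frame(death = rbinom(20, 1, 0.5), a = c(NA, rnorm(19)))
  expect_error(fit_logistic(death ~ a, d3), "missing values")
})

test_that("complete separation is flagged, not silently returned", {
  d <- data.frame(death = rep(c(0L, 1L), each = 20),
                  xvar = c(rnorm(20, -3), rnorm(20, 3)))
  fit <- fit_logistic(death ~ xvar, d)
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_equal(fit$separation_term, "xvar")
})

test_that("auto-logistic fit equals logistic fit on the augmented design", {
  ds <- small_dataset(n = 220, seed = 9)
  w <- ds$weights
  auto <- suppressWarnings(fit_autologistic(death ~ age + sex, ds$cohort, w))
  manual <- ds$cohort
  manual$autocovariate <-
    as.numeric(suppressWarnings(autocovariate(w, manual$death)))
  byhand <- fit_logistic(death ~ age + sex + autocovariate, manual)
  expect_equal(auto$terms$estimate, byhand$terms$estimate, tolerance = 1e-12)
  expect_equal(auto$gamma_term, "autocovariate")
  expect_true("autocovariate" %in% auto$terms$term)
})

test_that("a constant autocovariate raises a singular-design error", {
  # unit square with outcomes 1,0,0,1 around it and edge-only neighbours:
  # every corner sees one dead and one alive neighbour at distance 1, so
  # the autocovariate is 0.5 everywhere
  d <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                  death = c(1L, 0L, 0L, 1L), age = c(60, 70, 65, 75))
  w <- build_weights(d, radius = 1.2)
  expect_equal(var(as.numeric(autocovariate(w, d$death))), 0)
  expect_error(fit_autologistic(death ~ age, d, w),
               "autocovariate is constant")
})

test_that("fit serialization round-trips the coefficient table", {
  ds <- small_dataset(n = 200, seed = 21)
  fit <- fit_logistic(death ~ age + triage, ds$cohort)
  stem <- file.path(withr::local_tempdir(), "fit")
  write_fit(fit, stem, auc = auc_roc(fit$fitted, fit$outcome))
  back <- read.csv(paste0(stem, ".csv"))
  expect_equal(back$estimate, fit$terms$estimate, tolerance = 1e-12)
  card <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(card$aic, fit$aic, tolerance = 1e-12)
  expect_equal(card$n, fit$n)
})
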