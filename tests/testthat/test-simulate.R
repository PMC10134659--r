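test_that("the generator is fully determined by its configuration", {
  cfg <- sim_config(n = 120, seed = 33, n_neighborhoods = 10, n_blocks = 40)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$cohort, b$cohort)
  # and byte-identical on disk
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  # a different seed changes the draw
  c2 <- generate_dataset(sim_config(n = 120, seed = 34,
                                    n_neighborhoods = 10, n_blocks = 40))
  expect_false(identical(a$cohort$death, c2$cohort$death))
})

test_that("configured marginals are recovered at large n", {
  cfg <- sim_config(n = 10000, seed = 4)
  cohort <- sample_covariates(cfg)
  expect_lt(abs(mean(cohort$age) - 70), 0.5)
  expect_lt(abs(mean(cohort$triage == "levels12") - 0.691), 0.02)
  expect_lt(abs(mean(cohort$sex == "male") - 0.501), 0.02)
  expect_lt(abs(median(cohort$los) - 3), 1)
  # structural invariants
  expect_true(all(cohort$los >= 0))
  expect_true(all(cohort$age >= 18))
  expect_equal(cohort$revealed_access,
               cohort$response_time + cohort$transport_time)
  expect_true(all(cohort$delay_time >= 0 & cohort$screening_time >= 0))
  expect_true(all(is.na(cohort$death)))
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n = 5), "n")
  expect_error(sim_config(marginals = list(sex_male = 1.2)), "sex_male")
  expect_error(sim_config(marginals = list(age = c(70, -1))), "age")
  expect_error(sim_config(marginals = list(junk = 1)), "junk")
  expect_error(sim_config(gibbs_sweeps = 50, burn_in = 50), "burn_in")
  expect_error(sim_config(beta = c(age = 0.1)), "Intercept")
})

test_that("gamma = 0 decouples units into independent Bernoulli draws", {
  cfg <- sim_config(n = 400, gamma = 0, seed = 10,
                    n_neighborhoods = 15, n_blocks = 100)
  reps <- 25
  diffs <- vapply(seq_len(reps), function(r) {
    cfg$seed <- 100 + r
    ds <- generate_dataset(cfg)
    eta <- spautolog:::linear_predictor(ds$cohort, cfg$beta)
    mean(ds$cohort$death) - mean(plogis(eta))
  }, numeric(1))
  # empirical mortality within 2 SEs of the mean predicted probability
  se <- sd(diffs) / sqrt(reps)
  expect_lt(abs(mean(diffs)), 2 * se + 1e-3)
})

test_that("positive gamma induces positive spatial autocorrelation", {
  morans <- function(gamma, r) {
    cfg <- sim_config(n = 350, gamma = gamma, seed = 600 + r,
                      n_neighborhoods = 15, n_blocks = 100)
    ds <- generate_dataset(cfg)
    if (var(ds$cohort$death) == 0) return(NA_real_)
    global_morans_i(ds$weights, as.numeric(ds$cohort$death),
                    n_permutations = 99, seed = r)$statistic
  }
  i0 <- vapply(1:12, function(r) morans(0, r), numeric(1))
  i2 <- vapply(1:12, function(r) morans(2, r), numeric(1))
  expect_gt(mean(i2, na.rm = TRUE), mean(i0, na.rm = TRUE))
})

test_that("a hopeless linear predictor yields the degenerate-outcome warning", {
  cfg <- sim_config(n = 60, seed = 2, n_neighborhoods = 6, n_blocks = 20,
                    beta = c("(Intercept)" = -30))
  expect_warning(generate_dataset(cfg), "degenerate outcome")
  bad <- c("(Intercept)" = -2, nonexistent = 1)
  cfg2 <- sim_config(n = 60, seed = 2, n_neighborhoods = 6, n_blocks = 20,
                     beta = bad)
  expect_error(generate_dataset(cfg2), "nonexistent")
})

test_that("provenance JSON round-trips to an identical cohort", {
  cfg <- sim_config(n = 100, seed = 77, n_neighborhoods = 8, n_blocks = 30,
                    gamma = 0.5, radius = 200)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, dir = dir)
  cfg2 <- sim_config_from_json(file.path(dir, "provenance.json"))
  ds2 <- generate_dataset(cfg2)
  expect_identical(ds$cohort, ds2$cohort)
})

test_that("a minimal smoke cohort generates quickly", {
  t0 <- Sys.time()
  # at n = 10 an all-alive draw is likely; the degenerate-outcome warning is
  # expected behaviour, not a failure
  ds <- suppressWarnings(
    generate_dataset(sim_config(n = 10, seed = 1, n_neighborhoods = 3,
                                n_blocks = 5, radius = 5000)))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  expect_equal(nrow(ds$cohort), 10)
  expect_true(all(ds$cohort$death %in% 0:1))
})
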