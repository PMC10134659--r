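test_that("global Moran's I equals the brute-force double sum on small instances", {
  sizes <- c(4, 7, 10, 13, 16, 19, 22, 25)
  for (seed in 1:8) {
    inst <- random_instance(sizes[seed], seed)
    if (all(inst$weights$isolated)) next
    for (style in c("W", "B", "raw")) {
      got <- global_morans_i(inst$weights, inst$values,
                             n_permutations = 99, seed = 1, style = style)
      wm <- switch(style,
        W = row_standardize_dense(inst$weights),
        B = (as.matrix(inst$weights$w) > 0) * 1,
        raw = as.matrix(inst$weights$w))
      expect_equal(got$statistic, moran_brute(wm, inst$values),
                   tolerance = 1e-12)
    }
  }
})

test_that("global Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  inst <- random_instance(20, 99)
  got <- global_morans_i(inst$weights, inst$values, n_permutations = 99,
                         seed = 1)
  ref <- ape::Moran.I(inst$values, row_standardize_dense(inst$weights))
  expect_equal(got$statistic, ref$observed, tolerance = 1e-10)
  expect_equal(got$expected_null, ref$expected, tolerance = 1e-12)
})

test_that("expected null is -1/(n-1) and the pseudo p respects its floor", {
  inst <- random_instance(5, 3)
  got <- global_morans_i(inst$weights, inst$values, n_permutations = 99,
                         seed = 1)
  expect_equal(got$expected_null, -0.25)
  expect_gte(got$p_value, 1 / 100)
  expect_lte(got$p_value, 1)
})

test_that("two opposite-valued tight clusters give I = 1 with p at the floor", {
  pts <- data.frame(x = c(0, 1, 0, 1, 100, 101, 100, 101),
                    y = c(0, 0, 1, 1, 0, 0, 1, 1))
  vals <- c(1, 1, 1, 1, -1, -1, -1, -1)
  w <- build_weights(pts, radius = 5) # within-cluster pairs only
  got <- global_morans_i(w, vals, n_permutations = 999, seed = 7)
  expect_equal(got$statistic, 1, tolerance = 1e-12)
  expect_lte(got$p_value, 0.05)
})

test_that("Moran inputs are validated", {
  w <- toy_weights()
  expect_error(global_morans_i(w, c(1, 1, 1), 99), "zero variance")
  expect_error(global_morans_i(w, c(1, 2), 99), "length")
  expect_error(global_morans_i(w, c(1, 2, 3), n_permutations = 50), "99")
  iso <- build_weights(data.frame(x = c(0, 100), y = 0), radius = 1)
  expect_error(global_morans_i(iso, c(1, 2), 99), "isolated")
  expect_error(local_morans_i(w, c(2, 2, 2)), "zero variance")
})

test_that("permutation p-values are reproducible under a seed", {
  inst <- random_instance(15, 5)
  a <- global_morans_i(inst$weights, inst$values, 199, seed = 11)
  b <- global_morans_i(inst$weights, inst$values, 199, seed = 11)
  expect_identical(a$p_value, b$p_value)
})

test_that("local Moran decomposes the global statistic", {
  # sum_i I_i = I_global * S0 for the shared normalization
  for (seed in c(2, 13)) {
    inst <- random_instance(12, seed)
    if (any(inst$weights$isolated)) next
    lisa <- local_morans_i(inst$weights, inst$values, n_permutations = 99,
                           seed = 1)
    glob <- global_morans_i(inst$weights, inst$values, n_permutations = 99,
                            seed = 1)
    expect_equal(sum(lisa$local_i), glob$statistic * attr(lisa, "s0"),
                 tolerance = 1e-10)
  }
})

test_that("a lone high value among low neighbours is classified HL", {
  # one hot unit surrounded by a cold clique, plus a matching warm clique
  # far away so the centered values make the centre clearly high
  pts <- data.frame(x = c(0, 1, -1, 0, 0, 50, 51, 49, 50, 50),
                    y = c(0, 0, 0, 1, -1, 0, 0, 0, 1, -1))
  vals <- c(10, 0, 0, 0, 0, 5, 5, 5, 5, 5)
  w <- build_weights(pts, radius = 3)
  lisa <- local_morans_i(w, vals, n_permutations = 999, alpha = 0.1,
                         seed = 3)
  expect_lte(lisa$p_value[1], 0.1)
  expect_equal(as.character(lisa$cluster[1]), "HL")
  # non-significant units are labelled ns
  expect_true(all(as.character(lisa$cluster[lisa$p_value > 0.1]) == "ns"))
})

test_that("permutation test keeps its nominal size under the null", {
  # values shuffled independently of space: rejection near alpha = 0.05
  set.seed(314)
  pts <- data.frame(x = runif(40, 0, 100), y = runif(40, 0, 100))
  w <- build_weights(pts, radius = 30)
  rej <- vapply(1:120, function(r) {
    global_morans_i(w, rnorm(40), n_permutations = 99,
                    seed = 1000 + r)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.13)
})
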