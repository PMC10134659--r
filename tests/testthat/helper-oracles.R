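# Independent oracles and shared fixtures for the test suite.

# 3 collinear points at x = 0, 1, 2 with band radius 2.5:
# pairs (1,2) d=1, (2,3) d=1, (1,3) d=2 -> w = 1, 1, 0.5
toy_weights <- function() {
  build_weights(data.frame(x = c(0, 1, 2), y = 0), radius = 2.5)
}

# brute-force Moran's I straight from the double-sum definition, on a dense
# weight matrix; independent of the package's sparse implementation
moran_brute <- function(wm, values) {
  wm <- as.matrix(wm)
  n <- length(values)
  z <- values - mean(values)
  s0 <- sum(wm)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + wm[i, j] * z[i] * z[j]
    }
  }
  (n / s0) * num / sum(z^2)
}

# dense row-standardized matrix built independently of style_weights()
row_standardize_dense <- function(weights) {
  wm <- as.matrix(weights$w)
  rs <- rowSums(wm)
  rs[rs == 0] <- 1
  sweep(wm, 1, rs, "/") * (rowSums(as.matrix(weights$w)) > 0)
}

# trapezoidal integration of the empirical ROC curve; handles ties by
# stepping through unique thresholds
roc_trapezoid <- function(scores, outcome) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[outcome == 1] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[outcome == 0] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# random small spatial instance for oracle-equality checks
random_instance <- function(n, seed) {
  set.seed(seed)
  pts <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
  w <- build_weights(pts, radius = 40)
  values <- rnorm(n)
  list(weights = w, values = values)
}

# a small, fast synthetic dataset for unit tests
small_dataset <- function(n = 250, gamma = 1, seed = 42, ...) {
  generate_dataset(sim_config(n = n, gamma = gamma, seed = seed,
                              n_neighborhoods = 12, n_blocks = 70, ...))
}
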