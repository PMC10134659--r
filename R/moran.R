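#' Global Moran's I with permutation inference
#'
#' The cross-product statistic
#' \deqn{I = \frac{n}{S_0}\,
#'   \frac{\sum_i\sum_j w_{ij} z_i z_j}{\sum_i z_i^2},\qquad z_i = x_i-\bar x,}
#' computed over the stored distance-band weights (row-standardized by
#' default), with a pseudo p-value from random relabelling of the values
#' across locations. Under spatial independence the expectation of I is
#' \eqn{-1/(n-1)}.
#'
#' @param weights a [build_weights()] object.
#' @param values numeric vector with nonzero variance, one value per unit.
#' @param n_permutations number of random relabellings (>= 99; default 999).
#' @param seed optional seed making the permutation draw reproducible.
#' @param style weight styling: `"W"` row-standardized (default, the
#'   standard choice for irregular point data), `"B"` binary, `"raw"`
#'   unstandardized inverse distance.
#' @param alternative `"two.sided"` (default): pseudo p =
#'   (1 + #\{|I_perm - E| >= |I_obs - E|\}) / (1 + n_permutations);
#'   `"greater"`/`"less"` for one-sided clustering/dispersion alternatives.
#' @return A `moran_result`: list with `statistic`, `expected_null`
#'   (-1/(n-1)), `p_value`, `z_score` (relative to the permutation
#'   distribution), `n_permutations`, `alternative`, `n`.
#' @examples
#' w <- build_weights(data.frame(x = c(0, 1, 5, 6), y = 0), radius = 2)
#' global_morans_i(w, c(1, 2, 9, 8), n_permutations = 199, seed = 1)
#' @export
global_morans_i <- function(weights, values, n_permutations = 999,
                            seed = NULL, style = c("W", "B", "raw"),
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  prep <- moran_prepare(weights, values, n_permutations, style)
  obs <- moran_stat(prep$wm, prep$z, prep$s0)
  perm <- with_seed(seed, {
    zperm <- replicate(n_permutations, sample(prep$z))
    lag <- as.matrix(prep$wm %*% zperm)
    (prep$n / prep$s0) * colSums(zperm * lag) / sum(prep$z^2)
  })
  e0 <- -1 / (prep$n - 1)
  p <- switch(alternative,
    two.sided = (1 + sum(abs(perm - e0) >= abs(obs - e0))) / (1 + n_permutations),
    greater   = (1 + sum(perm >= obs)) / (1 + n_permutations),
    less      = (1 + sum(perm <= obs)) / (1 + n_permutations))
  out <- list(
    statistic = obs,
    expected_null = e0,
    p_value = p,
    z_score = (obs - mean(perm)) / sd(perm),
    n_permutations = n_permutations,
    alternative = alternative,
    n = prep$n
  )
  class(out) <- "moran_result"
  out
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Moran's I permutation test\n")
  cat(sprintf("  I = %.4f   E[I] = %.4f   z = %.2f\n",
              x$statistic, x$expected_null, x$z_score))
  cat(sprintf("  pseudo p = %.4g (%s, %d permutations, n = %d)\n",
              x$p_value, x$alternative, x$n_permutations, x$n))
  invisible(x)
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' Per-unit decomposition \eqn{I_i = z_i \sum_j w_{ij} z_j / m_2} with
#' \eqn{m_2 = \sum_k z_k^2 / n}; the sum of local statistics equals the
#' global I times \eqn{S_0}. Inference holds unit i fixed and permutes the
#' remaining values among its neighbours (conditional randomization).
#' Significant units are classified from the signs of the centered value and
#' its spatial lag into high-high (HH), low-low (LL), high-low (HL) and
#' low-high (LH) clusters/outliers.
#'
#' @inheritParams global_morans_i
#' @param alpha significance level for the cluster classification; units with
#'   pseudo p above `alpha` are labelled `"ns"`.
#' @return A data.frame of class `lisa_table` with columns `unit_id`,
#'   `local_i`, `p_value` (two-sided pseudo p) and `cluster` (factor with
#'   levels HH, LL, HL, LH, ns). Isolated units get `local_i = 0`,
#'   `p_value = NA` and class `"ns"`.
#' @export
local_morans_i <- function(weights, values, n_permutations = 999,
                           alpha = 0.05, seed = NULL,
                           style = c("W", "B", "raw")) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("`alpha` must lie in (0, 1)")
  }
  prep <- moran_prepare(weights, values, n_permutations, style)
  n <- prep$n
  z <- prep$z
  m2 <- sum(z^2) / n
  lag <- as.numeric(prep$wm %*% z)
  local_i <- z * lag / m2
  # neighbour lists in the styled weights
  wt <- methods::as(prep$wm, "TsparseMatrix")
  nb <- split(wt@j + 1L, factor(wt@i + 1L, levels = seq_len(n)))
  wl <- split(wt@x, factor(wt@i + 1L, levels = seq_len(n)))
  p_value <- rep(NA_real_, n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      k <- length(nb[[i]])
      if (k == 0L) next
      pool <- z[-i]
      wi <- wl[[i]]
      perm_lag <- vapply(seq_len(n_permutations), function(p) {
        sum(wi * pool[sample.int(n - 1L, k)])
      }, numeric(1))
      perm_i <- z[i] * perm_lag / m2
      e_i <- mean(perm_i)
      p_value[i] <- (1 + sum(abs(perm_i - e_i) >= abs(local_i[i] - e_i))) /
        (1 + n_permutations)
    }
  })
  cluster <- rep("ns", n)
  sig <- !is.na(p_value) & p_value <= alpha
  hi <- z > 0
  hi_lag <- lag > 0
  cluster[sig & hi & hi_lag] <- "HH"
  cluster[sig & !hi & !hi_lag] <- "LL"
  cluster[sig & hi & !hi_lag] <- "HL"
  cluster[sig & !hi & hi_lag] <- "LH"
  local_i[weights$isolated] <- 0
  out <- data.frame(
    unit_id = weights$ids,
    local_i = local_i,
    p_value = p_value,
    cluster = factor(cluster, levels = c("HH", "LL", "HL", "LH", "ns")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("lisa_table", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "s0") <- prep$s0
  out
}

# shared validation + styling for the Moran statistics
moran_prepare <- function(weights, values, n_permutations,
                          style = c("W", "B", "raw")) {
  stopifnot(inherits(weights, "distband_weights"))
  style <- match.arg(style)
  n <- length(weights$ids)
  if (length(values) != n) {
    stop_validation("values length does not match the number of units")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop_validation("values must be finite and complete")
  }
  if (var(values) == 0) {
    stop_validation("values have zero variance; Moran's I is undefined")
  }
  if (all(weights$isolated)) {
    stop_validation("all units are isolated; no pairs to correlate")
  }
  if (n_permutations < 99) {
    stop_validation("n_permutations must be at least 99")
  }
  wm <- style_weights(weights, style)
  list(wm = wm, z = values - mean(values), s0 = sum(wm), n = n)
}

moran_stat <- function(wm, z, s0) {
  n <- length(z)
  (n / s0) * sum(z * as.numeric(wm %*% z)) / sum(z^2)
}
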