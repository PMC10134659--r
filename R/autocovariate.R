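#' Inverse-distance autocovariate of a binary outcome
#'
#' For each unit i the autocovariate is the inverse-distance-weighted average
#' of its neighbours' outcomes,
#' \deqn{A_i = \frac{\sum_j w_{ij} y_j}{\sum_j w_{ij}},\qquad w_{ij}=1/d_{ij},}
#' a convex combination of neighbouring 0/1 outcomes, hence always in
#' \[0, 1\]. Appended as a covariate in a logistic model it yields the
#' auto-logistic (autologistic) model; fitting that model by ordinary
#' maximum likelihood is the pseudolikelihood estimator of the underlying
#' binary Markov random field.
#'
#' @param weights a [build_weights()] object.
#' @param outcome numeric 0/1 vector, one value per unit, in weights order.
#' @param fallback value assigned to isolated units (no neighbour inside the
#'   band): `"prevalence"` (default) uses the overall outcome mean, which
#'   keeps the design matrix complete without injecting spatial signal;
#'   `"na"` leaves `NA`.
#' @return numeric vector of autocovariate values with attribute
#'   `"isolated"` (logical). A warning reports isolated units.
#' @examples
#' w <- build_weights(data.frame(x = c(0, 1, 2), y = 0), radius = 2.5)
#' autocovariate(w, c(1, 0, 1))
#' @export
autocovariate <- function(weights, outcome, fallback = c("prevalence", "na")) {
  stopifnot(inherits(weights, "distband_weights"))
  fallback <- match.arg(fallback)
  n <- length(weights$ids)
  if (length(outcome) != n) {
    stop_validation("outcome length (", length(outcome),
                    ") does not match the number of units (", n, ")")
  }
  check_binary(outcome)
  rs <- Matrix::rowSums(weights$w)
  ac <- as.numeric(weights$w %*% outcome)
  ac <- ifelse(rs > 0, ac / ifelse(rs > 0, rs, 1), NA_real_)
  if (any(weights$isolated)) {
    warning(sum(weights$isolated), " isolated unit(s) received the '",
            fallback, "' autocovariate fallback", call. = FALSE)
    if (fallback == "prevalence") ac[weights$isolated] <- mean(outcome)
  }
  attr(ac, "isolated") <- weights$isolated
  ac
}
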