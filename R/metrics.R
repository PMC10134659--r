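#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed from midranks: the probability that a randomly chosen event
#' outranks a randomly chosen non-event, with ties counting one half. Equals
#' trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric risk scores or fitted probabilities.
#' @param outcome 0/1 vector of the same length, with both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_roc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)) # 0.75
#' @export
auc_roc <- function(scores, outcome) {
  if (length(scores) != length(outcome)) {
    stop_validation("scores and outcome lengths differ")
  }
  if (anyNA(scores) || !all(is.finite(scores))) {
    stop_validation("scores must be finite and complete")
  }
  check_binary(outcome)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    stop_validation("both outcome classes must be present to compute AUC")
  }
  r <- rank(scores) # midranks for ties
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Moran's I check on model residuals
#'
#' The standard diagnostic for residual spatial autocorrelation: extracts
#' residuals of the requested type from a fitted model and applies the
#' permutation Moran test over the distance-band weights. The default
#' alternative is `"greater"` — the diagnostic asks whether positive spatial
#' clustering remains in the residuals, and the conditional residuals of a
#' correctly specified auto-logistic model are mildly *negatively*
#' autocorrelated, which a two-sided test would flag spuriously.
#'
#' @param fit a converged `autolog_fit`.
#' @param weights a [build_weights()] object on the fitted units.
#' @param residual_type `"pearson"` (default), `"deviance"` or `"response"`.
#' @inheritParams global_morans_i
#' @return a [global_morans_i()] `moran_result`.
#' @export
residual_moran_check <- function(fit, weights,
                                 residual_type = c("pearson", "deviance",
                                                   "response"),
                                 n_permutations = 999, seed = NULL,
                                 style = c("W", "B", "raw"),
                                 alternative = c("greater", "two.sided",
                                                 "less")) {
  stopifnot(inherits(fit, "autolog_fit"))
  residual_type <- tryCatch(match.arg(residual_type), error = function(e) {
    stop_validation("unknown residual_type; valid types: ",
                    "pearson, deviance, response")
  })
  if (!fit$converged) {
    stop_validation("fit did not converge; residual diagnostics are not meaningful")
  }
  res <- residuals(fit$model, type = residual_type)
  global_morans_i(weights, as.numeric(res), n_permutations = n_permutations,
                  seed = seed, style = match.arg(style),
                  alternative = match.arg(alternative))
}

#' Compare two fitted models by AIC and AUC
#'
#' @param fit_a,fit_b converged `autolog_fit` objects on the same cohort and
#'   outcome.
#' @return An object of class `model_comparison`: list with per-model AIC and
#'   AUC, `delta_aic` (= AIC_b - AIC_a), `delta_auc`, and `preferred`
#'   (`"a"`, `"b"` or `"neither"`; lower AIC wins).
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "autolog_fit"), inherits(fit_b, "autolog_fit"))
  if (fit_a$n != fit_b$n) {
    stop_validation("models were fitted on different sample sizes (",
                    fit_a$n, " vs ", fit_b$n, "); AIC is not comparable")
  }
  if (!identical(fit_a$outcome, fit_b$outcome)) {
    stop_validation("models were fitted on different outcomes")
  }
  if (!fit_a$converged || !fit_b$converged) {
    stop_validation("both fits must have converged")
  }
  auc_a <- auc_roc(fit_a$fitted, fit_a$outcome)
  auc_b <- auc_roc(fit_b$fitted, fit_b$outcome)
  out <- list(
    aic_a = fit_a$aic, aic_b = fit_b$aic,
    auc_a = auc_a, auc_b = auc_b,
    delta_aic = fit_b$aic - fit_a$aic,
    delta_auc = auc_b - auc_a,
    preferred = if (fit_a$aic == fit_b$aic) "neither"
                else if (fit_b$aic < fit_a$aic) "b" else "a"
  )
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (lower AIC preferred)\n")
  cat(sprintf("  A: AIC = %.1f  AUC = %.3f\n", x$aic_a, x$auc_a))
  cat(sprintf("  B: AIC = %.1f  AUC = %.3f\n", x$aic_b, x$auc_b))
  cat(sprintf("  delta AIC (B - A) = %.2f   delta AUC = %.3f   preferred: %s\n",
              x$delta_aic, x$delta_auc, x$preferred))
  invisible(x)
}
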