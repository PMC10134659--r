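#' Fit a logistic regression model for a binary outcome
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, at a tight convergence tolerance) with the epidemiological
#' reporting surface: per-term odds ratios `exp(beta)` and Wald 95%
#' confidence intervals `exp(beta +/- 1.96 SE)`, model log-likelihood, AIC
#' and fitted probabilities. Categorical covariates are handled through
#' factor coding; the reference level is the first factor level.
#'
#' @param formula a model formula whose response is the 0/1 outcome, e.g.
#'   `death ~ age + sex + triage`.
#' @param data a data.frame (typically a cohort from [load_cohort()] or
#'   [generate_dataset()]) with no missing values in the modelled columns.
#' @param max_iterations IRLS iteration cap (default 50).
#' @return An object of class `autolog_fit`: list with `terms` (data.frame:
#'   term, estimate, se, z, p_value, or, ci_low, ci_high), `log_lik`, `aic`,
#'   `n`, `n_events`, `converged`, `separation` (logical; complete or
#'   quasi-complete separation detected, with the suspect term in
#'   `separation_term`), `fitted` (probabilities), `outcome`, `formula`, and
#'   the underlying `glm` object in `model`.
#' @details Complete separation is reported through `converged = FALSE` /
#'   `separation = TRUE` rather than an error, so callers can inspect the
#'   diverging term. A singular design (aliased columns) is an error naming
#'   the collinear columns. No penalization is applied.
#' @examples
#' d <- data.frame(y = rbinom(80, 1, 0.3), x = rnorm(80))
#' fit_logistic(y ~ x, d)
#' @export
fit_logistic <- function(formula, data, max_iterations = 50) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop_validation("columns not found in data: ",
                    paste(missing_cols, collapse = ", "))
  }
  if (anyNA(data[vars])) {
    bad <- vars[vapply(data[vars], anyNA, logical(1))]
    stop_validation("missing values in modelled columns: ",
                    paste(bad, collapse = ", "),
                    " (apply a complete-case filter first)")
  }
  y <- model_response(formula, data)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop_validation("outcome has no ",
                    if (sum(y) == 0) "events" else "non-events",
                    "; the logistic likelihood is degenerate")
  }
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = max_iterations)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop_validation("singular design: collinear column(s) ",
                    paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  separation <- sep_warned || !fit$converged || any(abs(cf) > 20)
  terms_df <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1],
    se = sm[, 2],
    z = sm[, 3],
    p_value = sm[, 4],
    or = exp(sm[, 1]),
    ci_low = exp(sm[, 1] - qnorm(0.975) * sm[, 2]),
    ci_high = exp(sm[, 1] + qnorm(0.975) * sm[, 2]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- list(
    terms = terms_df,
    log_lik = as.numeric(logLik(fit)),
    aic = AIC(fit),
    n = length(y),
    n_events = sum(y),
    converged = fit$converged && !separation,
    separation = separation,
    separation_term = if (separation) {
      terms_df$term[which.max(abs(terms_df$estimate))]
    } else NA_character_,
    fitted = as.numeric(fit$fitted.values),
    outcome = y,
    formula = formula,
    gamma_term = NA_character_,
    model = fit
  )
  class(out) <- "autolog_fit"
  out
}

#' Fit the auto-logistic model by maximum pseudolikelihood
#'
#' Computes the inverse-distance [autocovariate()] from the observed outcome,
#' appends it to the design as the covariate `autocovariate`, and fits the
#' augmented model with [fit_logistic()]. This is the pseudolikelihood
#' estimator of the autologistic binary Markov random field: the reported
#' standard error of the spatial coefficient gamma is pseudolikelihood-based
#' and does not account for the autocovariate being a function of the
#' outcome; it should be read as approximate.
#'
#' @inheritParams fit_logistic
#' @param weights a [build_weights()] object on the same units, in row order.
#' @param fallback isolated-unit fallback passed to [autocovariate()].
#' @return An `autolog_fit` whose `terms` include the `autocovariate` row
#'   (`gamma_term` marks it).
#' @export
fit_autologistic <- function(formula, data, weights,
                             fallback = c("prevalence", "na"),
                             max_iterations = 50) {
  stopifnot(inherits(weights, "distband_weights"))
  if (length(weights$ids) != nrow(data)) {
    stop_validation("weights and data cover different numbers of units")
  }
  y <- model_response(formula, data)
  ac <- autocovariate(weights, y, fallback = match.arg(fallback))
  if (var(ac) == 0) {
    stop_validation("singular design: autocovariate is constant ",
                    "(no outcome variation among neighbours)")
  }
  data$autocovariate <- as.numeric(ac)
  aug <- stats::update.formula(formula, . ~ . + autocovariate)
  out <- fit_logistic(aug, data, max_iterations = max_iterations)
  out$gamma_term <- "autocovariate"
  out$autocov <- as.numeric(ac)
  out
}

# extract and validate the 0/1 response of a model formula
model_response <- function(formula, data) {
  resp <- all.vars(formula[[2]])
  if (length(resp) != 1L || !resp %in% names(data)) {
    stop_validation("the formula response must be a single column of `data`")
  }
  y <- data[[resp]]
  check_binary(y, what = paste0("outcome `", resp, "`"))
  y
}

#' @export
print.autolog_fit <- function(x, digits = 2, ...) {
  kind <- if (!is.na(x$gamma_term)) "Auto-logistic (pseudolikelihood)"
          else "Logistic"
  cat(kind, "regression:",
      deparse(x$formula), "\n")
  cat(sprintf("  n = %d (%d events)   logLik = %.2f   AIC = %.1f%s\n",
              x$n, x$n_events, x$log_lik, x$aic,
              if (!x$converged) "   [NOT CONVERGED]" else ""))
  if (x$separation) {
    cat("  separation suspected; diverging term:", x$separation_term, "\n")
  }
  tab <- x$terms
  tab$`OR (95% CI)` <- sprintf(paste0("%.", digits, "f (%.", digits,
                                      "f-%.", digits, "f)"),
                               tab$or, tab$ci_low, tab$ci_high)
  print(data.frame(term = tab$term, `OR (95% CI)` = tab$`OR (95% CI)`,
                   p = signif(tab$p_value, 2), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' Tidy coefficient table of a fit
#'
#' @param fit an `autolog_fit`.
#' @return the per-term data.frame (term, estimate, se, z, p_value, or,
#'   ci_low, ci_high) at full precision.
#' @export
tidy_fit <- function(fit) {
  stopifnot(inherits(fit, "autolog_fit"))
  fit$terms
}

#' Serialize a fit as CSV plus a JSON model card
#'
#' Writes the tidy coefficient table to `<stem>.csv` and a model card
#' (n, events, logLik, AIC, convergence, optional AUC and residual-Moran p)
#' to `<stem>.json`.
#'
#' @param fit an `autolog_fit`.
#' @param stem output path without extension.
#' @param auc optional AUC to record.
#' @param residual_moran_p optional residual Moran pseudo p to record.
#' @return invisibly, the two paths written.
#' @export
write_fit <- function(fit, stem, auc = NULL, residual_moran_p = NULL) {
  stopifnot(inherits(fit, "autolog_fit"))
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  write.csv(fit$terms, csv, row.names = FALSE)
  card <- list(
    model = if (!is.na(fit$gamma_term)) "auto-logistic" else "logistic",
    formula = deparse(fit$formula),
    n = fit$n,
    n_events = fit$n_events,
    log_lik = fit$log_lik,
    aic = fit$aic,
    converged = fit$converged,
    separation = fit$separation
  )
  if (!is.null(auc)) card$auc <- auc
  if (!is.null(residual_moran_p)) card$residual_moran_p <- residual_moran_p
  jsonlite::write_json(card, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}
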