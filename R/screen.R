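#' Univariate screening of candidate covariates
#'
#' Stage one of the two-stage selection procedure: each candidate is fitted
#' alone against the outcome in a univariate logistic model and retained when
#' its p-value falls below `threshold` (0.25 by default, the conventional
#' liberal screen before a multivariable model). Single-degree-of-freedom
#' terms use the Wald test; categorical covariates with more than two levels
#' use a likelihood-ratio test of the whole term, so each candidate
#' contributes exactly one p-value.
#'
#' @param candidates character vector of column names to screen, in the order
#'   they should be reported.
#' @param data cohort data.frame containing `outcome` and the candidates.
#' @param outcome name of the 0/1 outcome column (default `"death"`).
#' @param threshold retention threshold on the p-value (default 0.25).
#' @return An object of class `screen_result`: data.frame with columns
#'   `candidate`, `df`, `p_value`, `retained`, plus attribute `selected`
#'   (character vector of retained candidates, input order preserved; also
#'   available via `selected()`). Candidates whose univariate fit fails are
#'   excluded with a warning naming them, not fatally.
#' @export
univariate_screen <- function(candidates, data, outcome = "death",
                              threshold = 0.25) {
  stopifnot(is.character(candidates), length(candidates) > 0,
            is.data.frame(data))
  if (!outcome %in% names(data)) {
    stop_validation("outcome column `", outcome, "` not found")
  }
  if (threshold <= 0 || threshold > 1) {
    stop_validation("`threshold` must lie in (0, 1]")
  }
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols)) {
    stop_validation("candidate column(s) not in data: ",
                    paste(missing_cols, collapse = ", "))
  }
  rows <- lapply(candidates, function(v) {
    res <- tryCatch({
      f <- reformulate(v, response = outcome)
      fit <- fit_logistic(f, data)
      multi <- is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) > 2 ||
        (is.character(data[[v]]) && length(unique(data[[v]])) > 2)
      if (multi) {
        # one p per variable: LR test of the whole term
        null <- glm(reformulate("1", response = outcome), data = data,
                    family = binomial())
        dev_diff <- null$deviance - fit$model$deviance
        df <- null$df.residual - fit$model$df.residual
        data.frame(candidate = v, df = df,
                   p_value = pchisq(dev_diff, df, lower.tail = FALSE))
      } else {
        data.frame(candidate = v, df = 1L,
                   p_value = fit$terms$p_value[nrow(fit$terms)])
      }
    }, error = function(e) {
      warning("candidate `", v, "` excluded: ", conditionMessage(e),
              call. = FALSE)
      data.frame(candidate = v, df = NA_integer_, p_value = NA_real_)
    })
    res
  })
  tab <- do.call(rbind, rows)
  tab$retained <- !is.na(tab$p_value) & tab$p_value < threshold
  class(tab) <- c("screen_result", "data.frame")
  attr(tab, "selected") <- tab$candidate[tab$retained]
  attr(tab, "threshold") <- threshold
  tab
}

#' Retained candidates of a screening result
#' @param screen a [univariate_screen()] result.
#' @return character vector of retained covariate names, input order.
#' @export
selected <- function(screen) {
  stopifnot(inherits(screen, "screen_result"))
  attr(screen, "selected")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Univariate screen (retain p < %.2f)\n", attr(x, "threshold")))
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  cat("selected:", paste(attr(x, "selected"), collapse = ", "), "\n")
  invisible(x)
}
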