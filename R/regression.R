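#' Multiple linear regression of an MMSE score on one EEG biomarker
#'
#' Fits `response ~ eeg_var + sex + age + edu` (5 parameters) and reports
#' the biomarker slope with its confidence interval and t-based p-value
#' (df = n - 5), the standardized coefficient
#' `beta* = beta * SD(eeg_var) / SD(response)` with a correspondingly
#' scaled interval, and the adjusted R-squared of the model.
#'
#' @param cohort data frame with `sex`, `age`, `edu`, the response column
#'   and the biomarker column.
#' @param response name of the MMSE total or domain score column.
#' @param eeg_var name of the biomarker column (`"mdf"`, `"pf"` or `"atr"`).
#' @param alpha significance level for the intervals.
#' @return A list of class `regression_result`: `beta`, `beta_ci`, `p`,
#'   `beta_std`, `beta_std_ci`, `adj_r2`, `df`, `n` and the fitted `model`.
#' @export
mlr_standardized <- function(cohort, response, eeg_var, alpha = 0.05) {
  d <- as.data.frame(cohort)
  for (v in c("sex", "age", "edu", response, eeg_var))
    if (is.null(d[[v]])) stop("missing column: ", v, call. = FALSE)
  n <- nrow(d)
  if (n <= 5) stop("need n > 5", call. = FALSE)
  d$.y <- d[[response]]; d$.x <- d[[eeg_var]]
  fit <- lm(.y ~ .x + sex + age + edu, data = d)
  if (any(is.na(coef(fit)))) stop("collinear predictors", call. = FALSE)
  sm <- summary(fit)
  beta <- coef(fit)[".x"]
  ci <- confint(fit, ".x", level = 1 - alpha)
  scale_f <- sd(d$.x) / sd(d$.y)
  structure(list(beta = unname(beta), beta_ci = as.numeric(ci),
                 p = sm$coefficients[".x", "Pr(>|t|)"],
                 beta_std = unname(beta) * scale_f,
                 beta_std_ci = as.numeric(ci) * scale_f,
                 adj_r2 = sm$adj.r.squared, df = fit$df.residual, n = n,
                 response = response, eeg_var = eeg_var, model = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s ~ %s + sex + age + edu (n = %d, df = %d)\n", x$response,
              x$eeg_var, x$n, x$df))
  cat(sprintf("  beta = %.3f (%.3f, %.3f), p = %.3g\n", x$beta,
              x$beta_ci[1], x$beta_ci[2], x$p))
  cat(sprintf("  beta* = %.3f (%.3f, %.3f), adj R2 = %.3f\n", x$beta_std,
              x$beta_std_ci[1], x$beta_std_ci[2], x$adj_r2))
  invisible(x)
}
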