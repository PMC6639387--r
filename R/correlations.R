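correlation_result <- function(estimate, n, ci, p, alpha, m, df = NULL) {
  structure(list(estimate = estimate, n = n, ci_low = ci[1], ci_high = ci[2],
                 p = p, alpha = alpha, bonferroni_m = m,
                 adjusted = m > 1, df = df),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (%d%% CI %.3f to %.3f), p = %.3g, n = %d%s\n",
              x$estimate, round(100 * (1 - x$alpha / x$bonferroni_m)),
              x$ci_low, x$ci_high, x$p, x$n,
              if (x$adjusted) sprintf(" [Bonferroni m = %d]", x$bonferroni_m) else ""))
  invisible(x)
}

#' Pearson correlation with Fisher-transform confidence interval
#'
#' Product-moment correlation with a confidence interval from the Fisher
#' z-transform and a two-sided t test. With `bonferroni_m > 1` the p-value
#' is multiplied by m (capped at 1) and the CI is widened to the
#' simultaneous `1 - alpha/m` level.
#'
#' @param x,y numeric vectors of equal length (n >= 4), finite values.
#' @param alpha family significance level (default 0.05).
#' @param bonferroni_m number of tests in the Bonferroni family.
#' @return A `correlation_result` with fields `estimate`, `n`, `ci_low`,
#'   `ci_high`, `p`, `adjusted`.
#' @export
#' @examples
#' pearson_ci(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
pearson_ci <- function(x, y, alpha = 0.05, bonferroni_m = 1) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in 'x' or 'y'", call. = FALSE)
  r <- cor(x, y)
  a <- alpha / bonferroni_m
  z <- atanh(min(max(r, -1), 1))
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(1 - a / 2) * se)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- min(1, bonferroni_m * 2 * pt(-abs(tval), n - 2))
  correlation_result(r, n, ci, p, alpha, bonferroni_m, df = n - 2)
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after linear regression on the
#' covariates (with intercept). Degrees of freedom are reduced by the
#' number of covariates: t and the Fisher CI use `n - k` in place of `n`.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix or data frame of k covariates (possibly
#'   zero columns, in which case the result equals [pearson_ci()]).
#' @inheritParams pearson_ci
#' @return A `correlation_result`.
#' @export
partial_pearson <- function(x, y, covariates, alpha = 0.05, bonferroni_m = 1) {
  z <- as.matrix(covariates)
  if (ncol(z) == 0L) return(pearson_ci(x, y, alpha, bonferroni_m))
  n <- length(x)
  k <- ncol(z)
  if (n <= k + 3) stop("need n > #covariates + 3", call. = FALSE)
  if (qr(cbind(1, z))$rank < k + 1)
    stop("collinear covariates", call. = FALSE)
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero residual variance", call. = FALSE)
  r <- cor(rx, ry)
  a <- alpha / bonferroni_m
  se <- 1 / sqrt(n - k - 3)
  ci <- tanh(atanh(r) + c(-1, 1) * qnorm(1 - a / 2) * se)
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- min(1, bonferroni_m * 2 * pt(-abs(tval), df))
  correlation_result(r, n, ci, p, alpha, bonferroni_m, df = df)
}

correlation_comparison <- function(delta, method, z, p, ci, raw_difference = NULL) {
  structure(list(delta = delta, method = method, z = z, p = p,
                 ci_low = ci[1], ci_high = ci[2],
                 raw_difference = raw_difference %||% delta),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("delta = %.3f (%s), z = %.3f, p = %.3g, CI %.3f to %.3f\n",
              x$delta, x$method, x$z, x$p, x$ci_low, x$ci_high))
  invisible(x)
}

check_r <- function(r, name, open = TRUE) {
  if (abs(r) > 1 || (open && abs(r) == 1))
    stop(sprintf("'%s' must satisfy |r| < 1", name), call. = FALSE)
  r
}

#' Fisher Z test for two independent correlations
#'
#' Tests `r1 = r2` for correlations estimated in two independent groups:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided.
#' The confidence interval for `r1 - r2` is Zou's modified-asymptotic
#' interval (its usual companion).
#'
#' @param r1,r2 sample correlations, |r| < 1.
#' @param n1,n2 group sizes (>= 4).
#' @param alpha significance level.
#' @param bonferroni_m Bonferroni family size (adjusts p and the CI level).
#' @return A `correlation_comparison` with `delta = r1 - r2`.
#' @export
fisher_z_independent <- function(r1, n1, r2, n2, alpha = 0.05,
                                 bonferroni_m = 1) {
  check_r(r1, "r1"); check_r(r2, "r2")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both groups", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- min(1, bonferroni_m * 2 * pnorm(-abs(z)))
  zou <- zou_ci_difference(r1, n1, r2, n2, alpha, bonferroni_m)
  correlation_comparison(r1 - r2, "fisher_independent", z, p,
                         c(zou$ci_low, zou$ci_high))
}

#' Zou's confidence interval for a difference of independent correlations
#'
#' Modified-asymptotic interval for `r1 - r2`: individual Fisher-transform
#' CIs `(l1, u1)` and `(l2, u2)` are combined as
#' `L = r1 - r2 - sqrt((r1-l1)^2 + (u2-r2)^2)` and
#' `U = r1 - r2 + sqrt((u1-r1)^2 + (r2-l2)^2)`.
#'
#' @inheritParams fisher_z_independent
#' @return A `correlation_comparison`; `z` and `p` are the Fisher Z test.
#' @export
zou_ci_difference <- function(r1, n1, r2, n2, alpha = 0.05, bonferroni_m = 1) {
  check_r(r1, "r1"); check_r(r2, "r2")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both groups", call. = FALSE)
  a <- alpha / bonferroni_m
  q <- qnorm(1 - a / 2)
  ci1 <- tanh(atanh(r1) + c(-1, 1) * q / sqrt(n1 - 3))
  ci2 <- tanh(atanh(r2) + c(-1, 1) * q / sqrt(n2 - 3))
  d <- r1 - r2
  lo <- d - sqrt((r1 - ci1[1])^2 + (ci2[2] - r2)^2)
  hi <- d + sqrt((ci1[2] - r1)^2 + (r2 - ci2[1])^2)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- min(1, bonferroni_m * 2 * pnorm(-abs(z)))
  correlation_comparison(d, "zou_independent", z, p, c(lo, hi))
}

#' Meng's Z test for two dependent correlations sharing a variable
#'
#' Compares `cor(x, y)` with `cor(z, y)` when both are computed on the same
#' sample (so they share variable `y` and are themselves correlated through
#' `cor(x, z)`), using the Meng-Rosenthal-Rubin statistic. The test and its
#' interval operate on the Fisher-z scale; `delta` is therefore
#' `atanh(r_xy) - atanh(r_zy)` (the raw correlation difference is kept in
#' `raw_difference`).
#'
#' @param r_xy,r_zy the two correlations with the shared variable y.
#' @param r_xz correlation between the non-shared variables.
#' @param n sample size (>= 4).
#' @param alpha significance level.
#' @param bonferroni_m Bonferroni family size.
#' @return A `correlation_comparison` with `method = "meng_dependent"`.
#' @export
meng_z_dependent <- function(r_xy, r_zy, r_xz, n, alpha = 0.05,
                             bonferroni_m = 1) {
  check_r(r_xy, "r_xy"); check_r(r_zy, "r_zy")
  if (abs(r_xz) > 1) stop("'r_xz' must satisfy |r| <= 1", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  R <- matrix(c(1, r_xz, r_xy, r_xz, 1, r_zy, r_xy, r_zy, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("infeasible correlation triple (not positive semi-definite)",
         call. = FALSE)
  rbar2 <- (r_xy^2 + r_zy^2) / 2
  f <- min((1 - r_xz) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  dz <- atanh(r_xy) - atanh(r_zy)
  se <- sqrt(2 * (1 - r_xz) * h / (n - 3))
  z <- dz / se
  a <- alpha / bonferroni_m
  p <- min(1, bonferroni_m * 2 * pnorm(-abs(z)))
  ci <- dz + c(-1, 1) * qnorm(1 - a / 2) * se
  correlation_comparison(dz, "meng_dependent", z, p, ci,
                         raw_difference = r_xy - r_zy)
}
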