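icc_point <- function(a, b) {
  # two-way absolute-agreement single-measure ICC, ICC(A,1), from the
  # mean squares of a subjects x raters ANOVA with k = 2 raters
  n <- length(a); k <- 2
  m <- cbind(a, b)
  grand <- mean(m)
  msr <- k * var(rowMeans(m))                          # between subjects
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)    # between raters
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Intraclass correlation (two-way absolute agreement, single measure)
#'
#' ICC(A,1) between two paired measurement series, with a percentile
#' bootstrap confidence interval obtained by resampling subjects (pairs)
#' with replacement.
#'
#' @param values_a,values_b numeric vectors of equal length (n >= 3).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap, or `NULL`.
#' @param alpha significance level of the percentile interval.
#' @return A list of class `agreement_result`: `icc`, `ci_low`, `ci_high`,
#'   `n`, `n_boot`.
#' @export
#' @examples
#' set.seed(1)
#' a <- rnorm(100); icc(a, a + rnorm(100, 0, 0.5), n_boot = 200, seed = 2)
icc <- function(values_a, values_b, n_boot = 1000, seed = NULL, alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) stop("lengths differ", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (var(c(a, b)) == 0) stop("zero total variance", call. = FALSE)
  est <- icc_point(a, b)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      icc_point(a[idx], b[idx])
    }, numeric(1)))
    ci <- quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                   names = FALSE)
  }
  structure(list(icc = est, ci_low = ci[1], ci_high = ci[2], n = n,
                 n_boot = n_boot), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (bootstrap 95%% CI %.3f to %.3f), n = %d\n",
              x$icc, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Paired t test with difference summary
#'
#' @param values_a,values_b numeric vectors of equal length (n >= 2).
#' @return A list: `mean_diff`, `sd_diff` (of a - b), `t`, `df`, `p`, `n`,
#'   plus `degenerate = TRUE` (with `t`, `p` set `NA`) when the differences
#'   have zero variance.
#' @export
paired_t <- function(values_a, values_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) stop("lengths differ", call. = FALSE)
  if (length(a) < 2) stop("need n >= 2", call. = FALSE)
  d <- a - b
  if (sd(d) == 0)
    return(list(mean_diff = mean(d), sd_diff = 0, t = NA_real_,
                df = length(d) - 1L, p = NA_real_, n = length(d),
                degenerate = TRUE))
  tt <- t.test(a, b, paired = TRUE)
  list(mean_diff = mean(d), sd_diff = sd(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = length(d),
       degenerate = FALSE)
}

#' Bland-Altman limits of agreement
#'
#' Mean difference and limits of agreement `mean +/- z[1-alpha/2] * SD` for
#' two paired measurement methods, with approximate confidence intervals
#' for the mean difference (`t` interval) and for each limit (standard
#' error `sqrt(3 s^2 / n)`). Plot data (pairwise means vs differences,
#' computed as `true - pred`) are included.
#'
#' @param true_vals,pred_vals numeric vectors of equal length (n >= 3).
#' @param alpha significance level (default 0.05, giving 1.96 SD limits).
#' @return A list of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `mean_diff_ci`, `loa_low_ci`, `loa_high_ci`,
#'   `n` and `plot_data` (data frame `mean`, `diff`).
#' @export
bland_altman <- function(true_vals, pred_vals, alpha = 0.05) {
  a <- as.numeric(true_vals); b <- as.numeric(pred_vals)
  if (length(a) != length(b)) stop("lengths differ", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  d <- a - b
  md <- mean(d); s <- sd(d)
  z <- qnorm(1 - alpha / 2)
  loa <- md + c(-1, 1) * z * s
  tq <- qt(1 - alpha / 2, n - 1)
  se_mean <- s / sqrt(n)
  se_loa <- sqrt(3 * s^2 / n)
  structure(list(mean_diff = md, sd_diff = s,
                 loa_low = loa[1], loa_high = loa[2],
                 mean_diff_ci = md + c(-1, 1) * tq * se_mean,
                 loa_low_ci = loa[1] + c(-1, 1) * tq * se_loa,
                 loa_high_ci = loa[2] + c(-1, 1) * tq * se_loa,
                 n = n,
                 plot_data = data.frame(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.3f +/- %.3f, LOA (%.3f, %.3f), n = %d\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference (true - predicted)", ...) {
  plot(x$plot_data$mean, x$plot_data$diff, xlab = xlab, ylab = ylab, ...)
  abline(h = x$mean_diff, lwd = 2)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}
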