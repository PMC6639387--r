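#' Cross-validated search over the lambda-alpha grid
#'
#' Stage-stratified 10-fold cross-validation on the training cohort over
#' all 300 x 11 = 3,300 penalized candidates (ridge alpha = 0, elastic net
#' 0 < alpha < 1, LASSO alpha = 1; 300 log-spaced lambdas from 10 to 1e-4)
#' plus the unpenalized least-squares model and its AIC-stepwise reduction.
#' The validation score of a candidate is the mean over folds of the
#' per-fold RMSE. Winners are reported per family (WLS, ridge, elastic net,
#' LASSO) and overall.
#'
#' @param train training cohort (a `cohort_table` or data frame with the
#'   biomarker, demographic and `mmse_total`, `stage` columns).
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param alphas mixing-parameter grid (default 0, 0.1, ..., 1).
#' @param lambdas regularization grid (default [lambda_grid()]).
#' @param spec optional [design_spec()]; defaults to one learned on `train`.
#' @param include_stepwise also cross-validate the AIC-reduced WLS model.
#' @return A list of class `cv_result`: `grid` (data frame `alpha`,
#'   `lambda`, `rmse` over the 3,300 candidates), `wls_rmse`,
#'   `wls_step_rmse`, `family_winners`, `winner` (model type, alpha,
#'   lambda, rmse), `spec`, `folds`, `k`, `seed`.
#' @export
cross_validate_grid <- function(train, k = 10, seed = NULL,
                                alphas = seq(0, 1, by = 0.1),
                                lambdas = lambda_grid(),
                                spec = NULL, include_stepwise = TRUE) {
  d <- as.data.frame(train)
  if (nrow(d) < 5 * k) stop("training set too small for ", k, " folds",
                            call. = FALSE)
  spec <- spec %||% design_spec(d)
  x <- build_design(spec, d)
  y <- d$mmse_total
  fold <- stratified_folds(d$stage, k, seed)
  for (f in seq_len(k))
    if (length(unique(d$stage[fold != f])) < length(unique(d$stage)))
      warning("fold ", f, " training part misses a stage; proceeding")

  n_lam <- length(lambdas)
  sqerr <- array(0, dim = c(length(alphas), n_lam))
  nv_tot <- 0L
  wls_se <- 0; wls_step_se <- 0
  wls_rmse_f <- numeric(k); wls_step_rmse_f <- numeric(k)
  rmse_fold <- array(0, dim = c(length(alphas), n_lam, k))
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xva <- x[!tr, , drop = FALSE]; yva <- y[!tr]
    nv <- length(yva); nv_tot <- nv_tot + nv
    for (ai in seq_along(alphas)) {
      mp <- glmnet_remap(ytr, alphas[ai], lambdas)
      fit <- glmnet::glmnet(xtr, ytr, alpha = mp$alpha, lambda = mp$lambda,
                            standardize = FALSE)
      pred <- predict(fit, newx = xva)   # nv x n_lam, in path order
      rmse_fold[ai, , f] <- sqrt(colMeans((yva - pred)^2))
    }
    w <- fit_wls(xtr, ytr, stepwise = include_stepwise)
    wls_rmse_f[f] <- sqrt(mean((yva - predict(w, xva, reduced = FALSE))^2))
    wls_step_rmse_f[f] <- if (include_stepwise)
      sqrt(mean((yva - predict(w, xva, reduced = TRUE))^2)) else NA_real_
  }
  rmse <- apply(rmse_fold, c(1, 2), mean)
  grid <- data.frame(alpha = rep(alphas, times = n_lam),
                     lambda = rep(lambdas, each = length(alphas)),
                     rmse = as.numeric(rmse))
  wls_rmse <- mean(wls_rmse_f)
  wls_step_rmse <- mean(wls_step_rmse_f)

  best_in <- function(rows) rows[which.min(rows$rmse), ]
  fam <- list(
    wls = data.frame(model = "wls", alpha = NA, lambda = NA,
                     rmse = if (include_stepwise) min(wls_rmse, wls_step_rmse)
                            else wls_rmse),
    ridge = cbind(model = "ridge", best_in(grid[grid$alpha == 0, ])),
    elastic_net = cbind(model = "elastic_net",
                        best_in(grid[grid$alpha > 0 & grid$alpha < 1, ])),
    lasso = cbind(model = "lasso", best_in(grid[grid$alpha == 1, ])))
  fam_df <- do.call(rbind, lapply(fam, function(r)
    data.frame(model = r$model, alpha = r$alpha, lambda = r$lambda,
               rmse = r$rmse)))
  rownames(fam_df) <- NULL
  winner <- fam_df[which.min(fam_df$rmse), ]
  structure(list(grid = grid, wls_rmse = wls_rmse,
                 wls_step_rmse = wls_step_rmse,
                 wls_used_stepwise = include_stepwise &&
                   wls_step_rmse <= wls_rmse,
                 family_winners = fam_df, winner = winner, spec = spec,
                 folds = fold, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV over %d penalized candidates + WLS\n",
              x$k, nrow(x$grid)))
  print(x$family_winners, digits = 4)
  invisible(x)
}

#' Held-out test-set evaluation of a prediction vector
#'
#' Agreement between observed and predicted MMSE on data never used for
#' fitting: RMSE, Pearson correlation with CI, mean difference (observed -
#' predicted) with SD, bootstrap ICC and Bland-Altman limits of agreement.
#'
#' @param y_test observed MMSE totals.
#' @param y_pred model predictions.
#' @param n_boot bootstrap replicates for the ICC interval.
#' @param seed bootstrap seed.
#' @return A list of class `prediction_evaluation`: `rmse`, `pearson`
#'   (a `correlation_result`), `mean_diff`, `sd_diff`, `icc`
#'   (an `agreement_result`), `bland_altman`, `n`.
#' @export
evaluate_predictions <- function(y_test, y_pred, n_boot = 1000, seed = NULL) {
  stopifnot(length(y_test) == length(y_pred))
  d <- y_test - y_pred
  structure(list(rmse = sqrt(mean(d^2)),
                 pearson = pearson_ci(y_test, y_pred),
                 mean_diff = mean(d), sd_diff = sd(d),
                 icc = icc(y_test, y_pred, n_boot = n_boot, seed = seed),
                 bland_altman = bland_altman(y_test, y_pred),
                 n = length(y_test)),
            class = "prediction_evaluation")
}

#' @export
print.prediction_evaluation <- function(x, ...) {
  cat(sprintf("test RMSE %.3f, r = %.3f (%.3f, %.3f), mean diff %.3f +/- %.3f, ICC %.3f\n",
              x$rmse, x$pearson$estimate, x$pearson$ci_low, x$pearson$ci_high,
              x$mean_diff, x$sd_diff, x$icc$icc))
  invisible(x)
}
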