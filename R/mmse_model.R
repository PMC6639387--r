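#' Fit the MMSE predictive model by stratified double cross-validation
#'
#' The full modelling procedure: (1) stage-stratified 80/20 train/test
#' split; (2) design construction on the training set (five standardized
#' continuous predictors with quadratic and sex-interaction terms, 21
#' columns plus intercept); (3) stage-stratified 10-fold cross-validation
#' of the WLS model and all 3,300 lambda-alpha penalized candidates;
#' (4) refit of each family's winner on the whole training set; (5) a
#' single evaluation of every family on the held-out test set (RMSE,
#' Pearson r, mean difference, bootstrap ICC, Bland-Altman). The overall
#' winner is the family with the smallest cross-validated RMSE.
#'
#' @param cohort a cohort table (see [simulate_cohort()] / [read_cohort()]).
#' @param test_fraction held-out fraction (default 0.2).
#' @param k folds (default 10).
#' @param seeds named list of integer seeds: `split`, `folds`, `boot`.
#' @param alphas,lambdas hyperparameter grids (defaults: 0 to 1 by 0.1;
#'   [lambda_grid()]).
#' @param include_stepwise cross-validate the AIC-reduced WLS variant too.
#' @param n_boot bootstrap replicates for test-set ICC intervals.
#' @param clip_predictions clip predicted MMSE into [0, 30] (off by
#'   default; raw linear predictions are reported as fitted).
#' @return An object of class `mmse_model` with components `cv`
#'   (a `cv_result`), `fits` (refitted winner per family), `evaluations`
#'   (a `prediction_evaluation` per family), `winner` (family name),
#'   `spec`, `split` and `seeds`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot` (Bland-Altman of the winner).
#' @export
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_sim_params(n_subjects = 300, seed = 1))
#' m <- fit_mmse_model(coh, seeds = list(split = 1, folds = 2, boot = 3))
#' print(m)
#' }
fit_mmse_model <- function(cohort, test_fraction = 0.2, k = 10,
                           seeds = list(split = 1L, folds = 2L, boot = 3L),
                           alphas = seq(0, 1, by = 0.1),
                           lambdas = lambda_grid(),
                           include_stepwise = TRUE, n_boot = 1000,
                           clip_predictions = FALSE) {
  sp <- stratified_split(cohort, test_fraction, seed = seeds$split)
  train <- as.data.frame(sp$train); test <- as.data.frame(sp$test)
  spec <- design_spec(train)
  cv <- cross_validate_grid(train, k = k, seed = seeds$folds,
                            alphas = alphas, lambdas = lambdas, spec = spec,
                            include_stepwise = include_stepwise)
  xtr <- build_design(spec, train); ytr <- train$mmse_total
  xte <- build_design(spec, test); yte <- test$mmse_total
  fw <- cv$family_winners
  fits <- list()
  for (i in seq_len(nrow(fw))) {
    fits[[fw$model[i]]] <- if (fw$model[i] == "wls")
      fit_wls(xtr, ytr, stepwise = include_stepwise)
    else fit_elastic_net(xtr, ytr, alpha = fw$alpha[i], lambda = fw$lambda[i])
  }
  predict1 <- function(fit, x) {
    p <- if (inherits(fit, "wls_fit"))
      predict(fit, x, reduced = cv$wls_used_stepwise)
    else predict(fit, x)
    if (clip_predictions) pmin(30, pmax(0, p)) else p
  }
  evaluations <- lapply(fits, function(f)
    evaluate_predictions(yte, predict1(f, xte), n_boot = n_boot,
                         seed = seeds$boot))
  structure(list(cv = cv, fits = fits, evaluations = evaluations,
                 winner = cv$winner$model, spec = spec, split = sp,
                 seeds = seeds, clip_predictions = clip_predictions,
                 y_test = yte,
                 y_test_pred = predict1(fits[[cv$winner$model]], xte)),
            class = "mmse_model")
}

#' Evaluate a fitted model on a held-out cohort
#'
#' @param fit a `penalized_fit` or `wls_fit`.
#' @param test held-out cohort rows.
#' @param spec the [design_spec()] learned on training data.
#' @param n_boot,seed bootstrap settings for the ICC interval.
#' @return A `prediction_evaluation`.
#' @export
evaluate_on_test <- function(fit, test, spec, n_boot = 1000, seed = NULL) {
  x <- build_design(spec, test)
  evaluate_predictions(as.data.frame(test)$mmse_total, predict(fit, x),
                       n_boot = n_boot, seed = seed)
}

#' @export
print.mmse_model <- function(x, ...) {
  cat("MMSE predictive model (stratified double cross-validation)\n")
  cat(sprintf("  train n = %d, test n = %d, %d-fold CV, %d penalized candidates\n",
              nrow(x$split$train), nrow(x$split$test), x$cv$k, nrow(x$cv$grid)))
  tab <- x$cv$family_winners
  tab$test_rmse <- vapply(tab$model, function(m) x$evaluations[[m]]$rmse, 1)
  tab$test_r <- vapply(tab$model, function(m) x$evaluations[[m]]$pearson$estimate, 1)
  tab$icc <- vapply(tab$model, function(m) x$evaluations[[m]]$icc$icc, 1)
  names(tab)[names(tab) == "rmse"] <- "cv_rmse"
  print(tab, digits = 4, row.names = FALSE)
  cat(sprintf("  selected: %s\n", x$winner))
  invisible(x)
}

#' @export
summary.mmse_model <- function(object, ...) {
  ev <- object$evaluations[[object$winner]]
  out <- list(winner = object$winner, cv_table = object$cv$family_winners,
              test = ev, coefficients = coef(object),
              n_train = nrow(object$split$train),
              n_test = nrow(object$split$test))
  class(out) <- "summary.mmse_model"
  out
}

#' @export
print.summary.mmse_model <- function(x, ...) {
  cat(sprintf("Selected model: %s (train %d / test %d)\n", x$winner,
              x$n_train, x$n_test))
  print(x$test)
  cat("Coefficients (standardized predictor scale):\n")
  print(round(x$coefficients[x$coefficients != 0], 4))
  invisible(x)
}

#' @export
coef.mmse_model <- function(object, model = object$winner, ...) {
  f <- object$fits[[model]]
  if (inherits(f, "wls_fit")) coef(f, reduced = object$cv$wls_used_stepwise)
  else coef(f)
}

#' @export
predict.mmse_model <- function(object, newdata, model = object$winner, ...) {
  x <- build_design(object$spec, newdata)
  f <- object$fits[[model]]
  p <- if (inherits(f, "wls_fit"))
    predict(f, x, reduced = object$cv$wls_used_stepwise)
  else predict(f, x)
  if (object$clip_predictions) pmin(30, pmax(0, p)) else p
}

#' @export
fitted.mmse_model <- function(object, ...) object$y_test_pred

#' @export
residuals.mmse_model <- function(object, ...) object$y_test - object$y_test_pred

#' @export
plot.mmse_model <- function(x, ...) {
  plot(x$evaluations[[x$winner]]$bland_altman,
       xlab = "Mean of observed and predicted MMSE",
       ylab = "Observed - predicted MMSE", ...)
}
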