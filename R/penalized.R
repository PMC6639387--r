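#' The lambda grid of the predictive-model search
#'
#' 300 log-spaced regularization values from 10 down to 1e-4.
#'
#' @param n_lambda number of values (default 300).
#' @param range upper and lower ends (default `c(10, 1e-4)`).
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(n_lambda = 300, range = c(10, 1e-4)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n_lambda))
}

# The elastic-net objective used throughout:
#   (1/2n) * RSS + lambda * [alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2]
# with an unpenalized intercept.
enet_objective <- function(x, y, intercept, beta, alpha, lambda) {
  r <- y - intercept - as.numeric(x %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# glmnet's gaussian path standardizes y internally by its 1/n standard
# deviation sy, which leaves the L1 penalty on the original scale but
# shrinks the effective L2 penalty by 1/sy. Requesting (alpha', lambda')
# with lambda' = lambda * (alpha + (1 - alpha) * sy) and
# alpha' = alpha * lambda / lambda' makes glmnet solve the objective above
# exactly at (alpha, lambda).
glmnet_remap <- function(y, alpha, lambda) {
  sy <- sqrt(mean((y - mean(y))^2))
  lam2 <- lambda * (alpha + (1 - alpha) * sy)
  a2 <- ifelse(lam2 > 0, alpha * lambda / lam2, alpha)
  list(alpha = unique(a2)[1], lambda = lam2, sy = sy)
}

#' Elastic-net / LASSO / ridge fit at one (alpha, lambda)
#'
#' Minimizes `(1/2n) RSS + lambda * [alpha ||b||_1 + (1-alpha)/2 ||b||_2^2]`
#' with an unpenalized intercept, on the design as given (the pipeline
#' standardizes predictors explicitly through [design_spec()], so no
#' further internal rescaling of columns is applied and coefficients are
#' reported on the standardized predictor scale). `alpha = 0` is ridge,
#' `alpha = 1` LASSO, intermediate values elastic net; `lambda = 0`
#' reproduces least squares.
#'
#' @param design numeric predictor matrix (no intercept column).
#' @param response numeric response.
#' @param alpha mixing parameter in [0, 1].
#' @param lambda regularization parameter (>= 0).
#' @param thresh glmnet convergence threshold.
#' @return A list of class `penalized_fit`: `alpha`, `lambda`, `intercept`,
#'   `beta` (named), `objective`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 50, 4); y <- rnorm(50, x[, 1])
#' fit <- fit_elastic_net(x, y, alpha = 1, lambda = 0.05)
#' coef(fit)
fit_elastic_net <- function(design, response, alpha, lambda, thresh = 1e-12) {
  x <- as.matrix(design); y <- as.numeric(response)
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]", call. = FALSE)
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  mp <- glmnet_remap(y, alpha, lambda)
  # decreasing warm-start path ending exactly at the requested value
  lam_hi <- max(mp$lambda * 1.01,
                max(abs(crossprod(scale(x, scale = FALSE),
                                  y - mean(y)))) / length(y))
  path <- if (mp$lambda > 0)
    exp(seq(log(lam_hi), log(mp$lambda), length.out = 25))
  else c(exp(seq(log(lam_hi), log(lam_hi * 1e-6), length.out = 24)), 0)
  path[length(path)] <- mp$lambda
  fit <- glmnet::glmnet(x, y, alpha = mp$alpha, lambda = path,
                        standardize = FALSE, thresh = thresh, maxit = 1e7)
  # the path ends exactly at the requested lambda: read off its column
  k <- length(path)
  cf <- c(unname(fit$a0[k]), as.numeric(fit$beta[, k]))
  beta <- stats::setNames(cf[-1], colnames(x))
  structure(list(alpha = alpha, lambda = lambda, intercept = cf[1],
                 beta = beta,
                 objective = enet_objective(x, y, cf[1], cf[-1], alpha, lambda)),
            class = "penalized_fit")
}

#' @export
coef.penalized_fit <- function(object, ...) c("(Intercept)" = object$intercept,
                                              object$beta)

#' @export
predict.penalized_fit <- function(object, newdata, ...) {
  object$intercept + as.numeric(as.matrix(newdata) %*% object$beta)
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("<penalized_fit> alpha = %g, lambda = %g, %d/%d nonzero slopes\n",
              x$alpha, x$lambda, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' Karush-Kuhn-Tucker residual of a penalized fit
#'
#' Largest violation of the subgradient optimality conditions of the
#' elastic-net objective at the fitted coefficients; near zero for an exact
#' solution.
#'
#' @param fit a [fit_elastic_net()] result.
#' @param design,response the data the fit was computed on.
#' @return Maximum absolute KKT violation.
#' @export
kkt_residual <- function(fit, design, response) {
  x <- as.matrix(design); y <- as.numeric(response)
  n <- length(y)
  r <- y - fit$intercept - as.numeric(x %*% fit$beta)
  g <- as.numeric(crossprod(x, r)) / n - fit$lambda * (1 - fit$alpha) * fit$beta
  viol <- numeric(length(g))
  nz <- fit$beta != 0
  viol[nz] <- abs(g[nz] - fit$lambda * fit$alpha * sign(fit$beta[nz]))
  viol[!nz] <- pmax(abs(g[!nz]) - fit$lambda * fit$alpha, 0)
  max(abs(mean(r)), viol)   # intercept stationarity plus slope conditions
}

#' Weighted least squares with AIC stepwise reduction
#'
#' Ordinary least squares on the design (unit weights unless `weights` is
#' given; no weighting scheme is imposed by default) plus a both-direction
#' stepwise search by AIC starting from the full model.
#'
#' @param design numeric predictor matrix with column names.
#' @param response numeric response.
#' @param weights optional observation weights.
#' @param stepwise run the AIC search (default TRUE).
#' @return A list of class `wls_fit`: `full` and `reduced` `lm` objects
#'   (`reduced = full` when `stepwise = FALSE`), `aic_full`, `aic_reduced`,
#'   `terms_kept`.
#' @export
fit_wls <- function(design, response, weights = NULL, stepwise = TRUE) {
  x <- as.matrix(design)
  if (nrow(x) <= ncol(x)) stop("need n > #columns", call. = FALSE)
  if (qr(cbind(1, x))$rank < ncol(x) + 1)
    stop("rank-deficient design", call. = FALSE)
  df <- data.frame(.y = as.numeric(response), x, check.names = TRUE)
  full <- if (is.null(weights)) lm(.y ~ ., data = df)
          else do.call(lm, list(.y ~ ., data = df, weights = weights))
  reduced <- if (stepwise) step(full, direction = "both", trace = 0) else full
  structure(list(full = full, reduced = reduced,
                 aic_full = stats::AIC(full), aic_reduced = stats::AIC(reduced),
                 terms_kept = setdiff(names(coef(reduced)), "(Intercept)")),
            class = "wls_fit")
}

#' @export
predict.wls_fit <- function(object, newdata, reduced = TRUE, ...) {
  nd <- as.data.frame(as.matrix(newdata), check.names = TRUE)
  unname(predict(if (reduced) object$reduced else object$full, newdata = nd))
}

#' @export
coef.wls_fit <- function(object, reduced = TRUE, ...) {
  coef(if (reduced) object$reduced else object$full)
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("<wls_fit> AIC full %.2f -> reduced %.2f (%d terms kept)\n",
              x$aic_full, x$aic_reduced, length(x$terms_kept)))
  invisible(x)
}
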