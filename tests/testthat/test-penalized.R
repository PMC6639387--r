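rand_problem <- function(n = 80, p = 6) {
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("v", seq_len(p))
  y <- rnorm(n, x %*% rnorm(p, 0, 0.7), 1)
  list(x = x, y = y)
}

test_that("lambda = 0 reproduces least squares for any alpha", {
  set.seed(41)
  for (a in c(0, 0.5, 1)) {
    pr <- rand_problem()
    fit <- fit_elastic_net(pr$x, pr$y, alpha = a, lambda = 0)
    ols <- coef(lm(pr$y ~ pr$x))
    expect_equal(unname(c(fit$intercept, fit$beta)), unname(ols),
                 tolerance = 1e-6)
  }
})

test_that("ridge matches the closed form on 50 random problems", {
  set.seed(42)
  for (i in 1:50) {
    pr <- rand_problem(n = sample(40:120, 1), p = sample(3:10, 1))
    lam <- exp(runif(1, log(1e-3), log(2)))
    fit <- fit_elastic_net(pr$x, pr$y, alpha = 0, lambda = lam)
    xc <- scale(pr$x, scale = FALSE)
    yc <- pr$y - mean(pr$y)
    n <- length(pr$y)
    bref <- solve(crossprod(xc) / n + lam * diag(ncol(xc)),
                  crossprod(xc, yc) / n)
    expect_equal(unname(fit$beta), as.numeric(bref), tolerance = 1e-6)
    expect_equal(fit$intercept, mean(pr$y) - sum(colMeans(pr$x) * fit$beta),
                 tolerance = 1e-6)
  }
})

test_that("LASSO zeroes every slope at and above the KKT threshold", {
  set.seed(43)
  for (i in 1:10) {
    pr <- rand_problem()
    n <- length(pr$y)
    xc <- scale(pr$x, scale = FALSE)
    lmax <- max(abs(crossprod(xc, pr$y - mean(pr$y)))) / n
    at <- fit_elastic_net(pr$x, pr$y, alpha = 1, lambda = lmax * 1.0001)
    expect_true(all(at$beta == 0))
    above <- fit_elastic_net(pr$x, pr$y, alpha = 1, lambda = lmax * 3)
    expect_true(all(above$beta == 0))
    below <- fit_elastic_net(pr$x, pr$y, alpha = 1, lambda = lmax * 0.8)
    expect_gt(sum(below$beta != 0), 0)
  }
})

test_that("solutions satisfy the subgradient conditions across the grid", {
  set.seed(44)
  pr <- rand_problem(n = 100, p = 8)
  for (a in c(0, 0.3, 0.7, 1)) for (lam in c(0.01, 0.1, 0.5)) {
    fit <- fit_elastic_net(pr$x, pr$y, alpha = a, lambda = lam)
    expect_lt(kkt_residual(fit, pr$x, pr$y), 1e-6)
  }
})

test_that("coefficient norms shrink as lambda grows at fixed alpha", {
  set.seed(45)
  pr <- rand_problem(n = 120, p = 8)
  for (a in c(0, 0.5, 1)) {
    lams <- c(0.01, 0.05, 0.2, 1, 4)
    norms <- vapply(lams, function(l)
      sum(abs(fit_elastic_net(pr$x, pr$y, alpha = a, lambda = l)$beta)),
      numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
    if (a == 1) {
      nnz <- vapply(lams, function(l)
        sum(fit_elastic_net(pr$x, pr$y, alpha = 1, lambda = l)$beta != 0),
        numeric(1))
      expect_true(all(diff(nnz) <= 0))            # sparsity non-decreasing
    }
  }
})

test_that("the objective agrees with an independent glmnet route", {
  skip_if_not_installed("glmnet")
  set.seed(46)
  pr <- rand_problem(n = 150, p = 6)
  fit <- fit_elastic_net(pr$x, pr$y, alpha = 1, lambda = 0.08)
  # pure-L1 case: glmnet's native objective coincides with ours
  ref <- glmnet::glmnet(pr$x, pr$y, alpha = 1, lambda = c(1, 0.3, 0.08),
                        standardize = FALSE, thresh = 1e-13)
  bref <- as.numeric(coef(ref, s = 0.08))
  expect_equal(unname(c(fit$intercept, fit$beta)), bref, tolerance = 1e-5)
})

test_that("least squares on an orthonormal design returns X'y", {
  set.seed(47)
  n <- 64
  raw <- matrix(rnorm(n * 5), n, 5)
  q <- qr.Q(qr(scale(raw, scale = FALSE)))        # orthonormal, mean-zero
  colnames(q) <- paste0("q", 1:5)
  y <- rnorm(n)
  fit <- fit_wls(q, y, stepwise = FALSE)
  expect_equal(unname(coef(fit)[-1]), as.numeric(crossprod(q, y)),
               tolerance = 1e-10)
  expect_equal(unname(coef(fit)[1]), mean(y), tolerance = 1e-10)
})

test_that("stepwise AIC keeps genuine terms and never worsens the AIC", {
  set.seed(48)
  kept_both <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    n <- 500
    x <- matrix(rnorm(n * 10), n, 10)
    colnames(x) <- paste0("t", 1:10)
    y <- 1 + 0.8 * x[, 2] - 0.6 * x[, 7] + rnorm(n, 0, 0.1)
    fit <- fit_wls(x, y)
    expect_lte(fit$aic_reduced, fit$aic_full + 1e-8)
    kept_both <- kept_both + all(c("t2", "t7") %in% fit$terms_kept)
  }
  expect_gte(kept_both / reps, 0.95)
})

test_that("weights are honoured and rank deficiency is caught", {
  set.seed(49)
  x <- matrix(rnorm(200), 100, 2); colnames(x) <- c("a", "b")
  y <- rnorm(100, x[, 1])
  w <- runif(100, 0.5, 2)
  fit <- fit_wls(x, y, weights = w, stepwise = FALSE)
  ref <- lm(y ~ x, weights = w)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  xd <- cbind(x, c = x[, 1] * 2)
  expect_error(fit_wls(xd, y), "rank")
})
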