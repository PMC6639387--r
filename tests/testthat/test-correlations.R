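test_that("pearson_ci reproduces hand and cor.test values", {
  r <- pearson_ci(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$estimate, 0.8)                    # product-moment by hand
  x <- 1:20
  expect_equal(pearson_ci(x, x)$estimate, 1)
  neg <- pearson_ci(x, -x)
  expect_equal(neg$estimate, -1)
  expect_lt(neg$p, 1e-12)
  set.seed(2)
  a <- rnorm(60); b <- rnorm(60, a)
  mine <- pearson_ci(a, b)
  ref <- cor.test(a, b)
  expect_equal(mine$estimate, unname(ref$estimate))
  expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_error(pearson_ci(rep(1, 10), rnorm(10)), "variance")
})

test_that("Bonferroni adjustment scales p and widens the interval", {
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50, 0.4 * a)
  plain <- pearson_ci(a, b)
  adj <- pearson_ci(a, b, bonferroni_m = 3)
  expect_equal(adj$p, min(1, 3 * plain$p))
  expect_lt(adj$ci_low, plain$ci_low)
  expect_gt(adj$ci_high, plain$ci_high)
  # the adjusted CI is the 1 - alpha/m Fisher interval
  manual <- tanh(atanh(plain$estimate) +
                   c(-1, 1) * qnorm(1 - 0.05 / 6) / sqrt(50 - 3))
  expect_equal(c(adj$ci_low, adj$ci_high), manual, tolerance = 1e-12)
})

test_that("partial correlation matches the one-covariate closed form", {
  set.seed(4)
  n <- 200
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + rnorm(n)
  est <- partial_pearson(x, y, cbind(z))$estimate
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(est, closed, tolerance = 1e-12)
  # no covariates reduces to the plain correlation
  expect_equal(partial_pearson(x, y, matrix(numeric(0), n, 0))$estimate,
               pearson_ci(x, y)$estimate)
  # y driven by the covariate only, x independent: estimate near zero
  w <- rnorm(1000)
  y2 <- w + rnorm(1000, sd = 0.3)
  x2 <- rnorm(1000)
  expect_lt(abs(partial_pearson(x2, y2, cbind(w))$estimate), 0.1)
  expect_error(partial_pearson(x, y, cbind(z, 2 * z)), "collinear")
})

test_that("partial correlation is invariant to affine covariate rescaling", {
  set.seed(5)
  n <- 150
  cov1 <- cbind(sex = rbinom(n, 1, 0.5), age = runif(n, 50, 90),
                edu = runif(n, 0, 18))
  x <- rnorm(n, 0.02 * cov1[, "age"])
  y <- rnorm(n, 0.1 * cov1[, "edu"])
  cov2 <- cbind(cov1[, 1] * 3 - 1, cov1[, 2] / 10 + 5, cov1[, 3] * 0.5)
  a <- partial_pearson(x, y, cov1)
  b <- partial_pearson(x, y, cov2)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("Fisher Z comparison matches the closed form and is antisymmetric", {
  cmp <- fisher_z_independent(0.5, 100, 0.2, 100)
  z_hand <- (atanh(0.5) - atanh(0.2)) / sqrt(1 / 97 + 1 / 97)
  expect_equal(cmp$z, z_hand, tolerance = 1e-12)
  expect_equal(cmp$z, 2.4136, tolerance = 1e-4)
  expect_equal(cmp$delta, 0.3)
  same <- fisher_z_independent(0.4, 80, 0.4, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  swapped <- fisher_z_independent(0.2, 100, 0.5, 100)
  expect_equal(swapped$z, -cmp$z)
  expect_error(fisher_z_independent(1, 100, 0.5, 100), "\\|r\\| < 1")
})

test_that("Zou interval is symmetric under equal inputs and widens with less data", {
  eq <- zou_ci_difference(0.4, 100, 0.4, 100)
  expect_equal(eq$ci_low, -eq$ci_high, tolerance = 1e-12)
  expect_lte(eq$ci_low, eq$delta); expect_gte(eq$ci_high, eq$delta)
  full <- zou_ci_difference(0.5, 200, 0.3, 200)
  half <- zou_ci_difference(0.5, 100, 0.3, 100)
  expect_gt(half$ci_high - half$ci_low, full$ci_high - full$ci_low)
})

test_that("Meng test is zero at equal correlations and flips with its arguments", {
  eq <- meng_z_dependent(0.4, 0.4, 0.3, 200)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  a <- meng_z_dependent(0.5, 0.3, 0.4, 200)
  b <- meng_z_dependent(0.3, 0.5, 0.4, 200)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_lte(a$ci_low, a$delta); expect_gte(a$ci_high, a$delta)
  expect_error(meng_z_dependent(0.9, -0.9, 0.9, 100), "infeasible")
})
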