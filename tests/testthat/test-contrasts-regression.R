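test_that("contrast degrees of freedom equal n minus the 8 model parameters", {
  coh <- cohort_with_stages(162, 179, 155, seed = 21)   # n = 496
  res <- marginal_means_contrasts(coh, "mdf")
  expect_equal(res$df_residual, 488)
  expect_true(all(res$contrasts$df == 488))
  expect_equal(nrow(res$contrasts), 4)                  # 2 contrasts x 2 sexes
  expect_setequal(unique(as.character(res$contrasts$contrast)),
                  c("T2 - T3", "T1 - T2"))
  expect_true(all(res$contrasts$ci_low <= res$contrasts$estimate &
                    res$contrasts$estimate <= res$contrasts$ci_high))
})

test_that("marginal means equal raw cell means in a balanced design", {
  # identical covariate values replicated in every sex-stage cell, response
  # driven by the cell only: the covariate adjustment cancels exactly
  set.seed(22)
  per_cell <- 20
  ages <- runif(per_cell, 55, 85); edus <- runif(per_cell, 0, 16)
  cells <- expand.grid(sex = 0:1, stage = c("T3", "T2", "T1"))
  d <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(sex = cells$sex[i], stage = cells$stage[i],
               age = ages, edu = edus)))
  d$mdf <- 8 + 0.5 * (d$stage == "T3") - 0.4 * (d$stage == "T1") + rnorm(nrow(d), 0, 0.3)
  res <- marginal_means_contrasts(d, "mdf")
  raw <- aggregate(mdf ~ stage + sex, data = d, FUN = mean)
  mm <- res$marginal_means
  for (i in seq_len(nrow(mm))) {
    r <- raw$mdf[raw$stage == as.character(mm$stage[i]) &
                   raw$sex == as.character(mm$sex[i])]
    expect_equal(mm$emmean[i], r, tolerance = 1e-10)
  }
})

test_that("marginal means and contrasts match a normal-equations oracle", {
  set.seed(23)
  coh <- cohort_with_stages(40, 40, 40, seed = 23)
  res <- marginal_means_contrasts(coh, "pf")
  d <- as.data.frame(coh)
  d$stage <- factor(d$stage, levels = c("T3", "T2", "T1"))
  d$sex <- factor(d$sex)
  X <- model.matrix(~ sex * stage + age + edu, data = d)
  y <- d$pf
  beta <- solve(crossprod(X), crossprod(X, y))
  sigma2 <- sum((y - X %*% beta)^2) / (nrow(X) - ncol(X))
  covb <- sigma2 * solve(crossprod(X))
  # prediction rows for each sex-stage cell at whole-sample mean age/edu
  cell_row <- function(sex, stage) {
    nd <- data.frame(sex = factor(sex, levels = levels(d$sex)),
                     stage = factor(stage, levels = levels(d$stage)),
                     age = mean(d$age), edu = mean(d$edu))
    model.matrix(delete.response(terms(~ sex * stage + age + edu)), nd)
  }
  for (i in seq_len(nrow(res$marginal_means))) {
    mmrow <- res$marginal_means[i, ]
    r <- cell_row(as.character(mmrow$sex), as.character(mmrow$stage))
    expect_equal(mmrow$emmean, as.numeric(r %*% beta), tolerance = 1e-8)
    expect_equal(mmrow$SE, sqrt(as.numeric(r %*% covb %*% t(r))),
                 tolerance = 1e-8)
  }
  # consecutive contrast T1 - T2 for sex 0, with its covariance-based SE
  cvec <- cell_row("0", "T1") - cell_row("0", "T2")
  est <- as.numeric(cvec %*% beta)
  se <- sqrt(as.numeric(cvec %*% covb %*% t(cvec)))
  row <- res$contrasts[res$contrasts$contrast == "T1 - T2" &
                         res$contrasts$sex == "0", ]
  expect_equal(row$estimate, est, tolerance = 1e-8)
  expect_equal(row$se, se, tolerance = 1e-8)
  expect_equal(row$t, est / se, tolerance = 1e-8)
})

test_that("an injected stage drop is recovered by its simultaneous CI", {
  set.seed(24)
  hits <- 0; reps <- 120
  for (r in seq_len(reps)) {
    n_cell <- 40
    d <- expand.grid(sex = 0:1, stage = c("T3", "T2", "T1"),
                     k = seq_len(n_cell))
    d$age <- runif(nrow(d), 50, 90)
    d$edu <- runif(nrow(d), 0, 18)
    mu <- c(T3 = 9, T2 = 8.8, T1 = 8.3)             # T1 - T2 = -0.5
    d$mdf <- mu[as.character(d$stage)] + 0.01 * (d$age - 70) + rnorm(nrow(d), 0, 0.8)
    res <- marginal_means_contrasts(d, "mdf")
    rows <- res$contrasts[res$contrasts$contrast == "T1 - T2", ]
    hits <- hits + all(rows$ci_low <= -0.5 & -0.5 <= rows$ci_high)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("standardized MLR has the stated df, identities and invariances", {
  coh <- cohort_with_stages(162, 179, 155, seed = 25)   # n = 496
  m <- mlr_standardized(coh, "mmse_total", "mdf")
  expect_equal(m$df, 491)
  expect_equal(sign(m$beta), sign(m$beta_std))
  expect_lte(m$adj_r2, 1)

  # exact linear response: slope 2, perfect fit, standardized slope 1
  d <- cohort_with_stages(30, 30, 30, seed = 26)
  d$mmse_like <- 2 * d$mdf
  # an exact fit makes summary.lm warn about its own reliability; expected here
  ex <- suppressWarnings(mlr_standardized(d, "mmse_like", "mdf"))
  expect_equal(ex$beta, 2, tolerance = 1e-8)
  expect_equal(ex$beta_std, 1, tolerance = 1e-8)
  expect_equal(ex$adj_r2, 1, tolerance = 1e-8)

  # standardized coefficient is invariant to rescaling the biomarker
  d2 <- d
  d2$mdf <- d2$mdf * 10
  d2$mmse_like <- d$mmse_like
  set.seed(27)
  d$noisy <- d$mmse_total + rnorm(nrow(d))
  d2$noisy <- d$noisy
  a <- mlr_standardized(d, "noisy", "mdf")
  b <- mlr_standardized(d2, "noisy", "mdf")
  expect_equal(a$beta_std, b$beta_std, tolerance = 1e-10)
  expect_equal(a$adj_r2, b$adj_r2, tolerance = 1e-10)
  expect_equal(a$beta, 10 * b$beta, tolerance = 1e-10)
})
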