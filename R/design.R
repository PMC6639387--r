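#' Standardize values with training-set parameters
#'
#' `z = (x - mean(train)) / sd(train)`; new data are always transformed
#' with the parameters learned on the training values only.
#'
#' @param train_values numeric vector defining mean and SD (SD must be > 0).
#' @param apply_values values to transform (defaults to the training values).
#' @return `list(values, mean, sd)`.
#' @export
#' @examples
#' s <- standardize(c(1, 2, 3, 4))
#' s$values
standardize <- function(train_values, apply_values = train_values) {
  m <- mean(train_values); s <- sd(train_values)
  if (!is.finite(s) || s == 0)
    stop("training values have zero standard deviation", call. = FALSE)
  list(values = (apply_values - m) / s, mean = m, sd = s)
}

PREDICTORS <- c("mdf", "pf", "atr", "age", "edu")

#' Design-matrix specification for the MMSE predictive models
#'
#' Learns the standardization parameters (means and SDs of the five
#' continuous predictors MDF, PF, ATR, age, education) on a training
#' cohort. [build_design()] then produces, for any cohort, the 21-column
#' design: `sex`, plus for each standardized predictor X the terms X, X^2,
#' sex:X and sex:X^2 (quadratics and sex interactions of every continuous
#' predictor). The intercept is handled by the fitting routines.
#'
#' @param train a cohort table (training rows only).
#' @param predictors continuous predictor columns (default the five above).
#' @return A list of class `design_spec` with `means`, `sds`, `predictors`.
#' @export
design_spec <- function(train, predictors = PREDICTORS) {
  d <- as.data.frame(train)
  means <- vapply(predictors, function(v) mean(d[[v]]), numeric(1))
  sds <- vapply(predictors, function(v) sd(d[[v]]), numeric(1))
  if (any(sds == 0)) stop("constant predictor column", call. = FALSE)
  structure(list(means = means, sds = sds, predictors = predictors),
            class = "design_spec")
}

#' Build the model design matrix for a cohort
#'
#' @param spec a [design_spec()] learned on training data.
#' @param cohort cohort rows to transform (training or test).
#' @return Numeric matrix (no intercept column) with columns `sex` and, for
#'   each predictor X: `X`, `X2`, `sex_X`, `sex_X2`.
#' @export
build_design <- function(spec, cohort) {
  d <- as.data.frame(cohort)
  sex <- as.numeric(d$sex)
  cols <- list(sex = sex)
  for (v in spec$predictors) {
    z <- (d[[v]] - spec$means[[v]]) / spec$sds[[v]]
    cols[[v]] <- z
    cols[[paste0(v, "2")]] <- z^2
    cols[[paste0("sex_", v)]] <- sex * z
    cols[[paste0("sex_", v, "2")]] <- sex * z^2
  }
  do.call(cbind, cols)
}
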