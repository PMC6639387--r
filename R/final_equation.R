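# Published final LASSO model (lambda = 0.007, alpha = 1): one polynomial
# per sex, sharing the intercept and the linear MDF and Age terms.
FINAL_EQUATION <- list(
  male = c(intercept = 24.597, mdf = 7.216, mdf2 = -6.318, pf = -0.013,
           pf2 = 0, atr = 0.913, atr2 = -0.930, age = 4.192, age2 = -5.060,
           edu = 4.725, edu2 = -2.523),
  female = c(intercept = 24.597, mdf = 7.216, mdf2 = -6.343, pf = 0.008,
             pf2 = 0.400, atr = 1.525, atr2 = -0.939, age = 4.192,
             age2 = -5.502, edu = 3.277, edu2 = -1.476))

#' Predicted MMSE from the published final LASSO equations
#'
#' Evaluates the final sex-specific polynomial prediction equations at
#' standardized predictor values. All continuous inputs must already be on
#' the standardized (mean 0, SD 1) scale of the model's training data.
#' Inputs are vectorized and recycled to a common length.
#'
#' @param mdf_std,pf_std,atr_std,age_std,edu_std standardized predictors.
#' @param sex 1 for female, 0 for male.
#' @return Predicted MMSE score(s), unclipped.
#' @export
#' @examples
#' predict_final_equation(0, 0, 0, 0, 0, sex = 0)  # the shared intercept
#' predict_final_equation(1, 0, 0, 0, 0, sex = 0)
predict_final_equation <- function(mdf_std, pf_std, atr_std, age_std,
                                   edu_std, sex) {
  if (!all(sex %in% c(0, 1))) stop("'sex' must be 0 (male) or 1 (female)",
                                   call. = FALSE)
  args <- cbind(mdf = mdf_std, pf = pf_std, atr = atr_std, age = age_std,
                edu = edu_std, sex = sex)
  apply(args, 1, function(r) {
    cf <- if (r[["sex"]] == 1) FINAL_EQUATION$female else FINAL_EQUATION$male
    cf[["intercept"]] +
      cf[["mdf"]] * r[["mdf"]] + cf[["mdf2"]] * r[["mdf"]]^2 +
      cf[["pf"]] * r[["pf"]] + cf[["pf2"]] * r[["pf"]]^2 +
      cf[["atr"]] * r[["atr"]] + cf[["atr2"]] * r[["atr"]]^2 +
      cf[["age"]] * r[["age"]] + cf[["age2"]] * r[["age"]]^2 +
      cf[["edu"]] * r[["edu"]] + cf[["edu2"]] * r[["edu"]]^2
  })
}
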