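#' Parameters for the synthetic cohort generator
#'
#' Controls [simulate_cohort()]. Each subject carries a latent "slowing"
#' scalar that increases with age and drives, jointly, a lower dominant
#' peak frequency and a higher theta-to-alpha amplitude balance, so the
#' three EEG biomarkers co-move the way prefrontal slowing does. The MMSE
#' total is a rounded, clipped linear combination of standardized
#' predictors plus Gaussian noise.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param coeffs named numeric vector of true effects (MMSE points per SD
#'   of predictor) on the latent MMSE scale. Recognised names:
#'   `slowing`, `mdf`, `pf`, `atr`, `age`, `edu`, `sex` (sex enters as the
#'   0/1 indicator, not standardized).
#' @param intercept latent MMSE mean at predictor means (default 25,
#'   matching a community-dwelling elderly cohort).
#' @param noise_sd residual SD of the latent MMSE in points (> 0).
#' @param sex_ratio fraction of female subjects, in [0, 1].
#' @param age_range,edu_range uniform sampling ranges in years; degenerate
#'   (reversed or zero-width) ranges are rejected.
#' @param eeg_params baseline [eeg_sim_params()] whose `peak_freq`,
#'   `alpha_amp` and `theta_amp` are modulated per subject by the latent
#'   slowing. Its `duration_s`/`fs` apply to generated recordings. The
#'   default uses a 0.4 Hz alpha linewidth: real eyes-closed alpha peaks
#'   are broad, which is what separates the median from the peak frequency
#'   in extracted biomarkers.
#' @param seed integer seed or `NULL`.
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_subjects = 100,
                              coeffs = c(slowing = -2.2, age = -1.0, edu = 1.1),
                              intercept = 25, noise_sd = 2.7,
                              sex_ratio = 2 / 3,
                              age_range = c(50, 90), edu_range = c(0, 18),
                              eeg_params = eeg_sim_params(alpha_linewidth = 0.4),
                              seed = NULL) {
  if (n_subjects < 2) stop("'n_subjects' must be >= 2", call. = FALSE)
  if (noise_sd <= 0) stop("'noise_sd' must be > 0", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("'sex_ratio' must lie in [0, 1]", call. = FALSE)
  for (r in list(age_range = age_range, edu_range = edu_range))
    if (length(r) != 2L || diff(r) <= 0)
      stop("ranges must be increasing length-2 vectors", call. = FALSE)
  known <- c("slowing", "mdf", "pf", "atr", "age", "edu", "sex")
  if (length(coeffs) && (is.null(names(coeffs)) || !all(names(coeffs) %in% known)))
    stop("'coeffs' must be named with a subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  structure(list(n_subjects = n_subjects, coeffs = coeffs,
                 intercept = intercept, noise_sd = noise_sd,
                 sex_ratio = sex_ratio, age_range = age_range,
                 edu_range = edu_range, eeg_params = eeg_params, seed = seed),
            class = "cohort_sim_params")
}

#' Allocate an MMSE total over the eight domain scores
#'
#' Splits an integer total in [0, 30] across the eight MMSE domains
#' proportionally to their maxima (5, 5, 3, 5, 3, 6, 1, 2), by flooring the
#' proportional quota and then handing out the remaining points one at a
#' time in a fixed priority order starting with orientation to time (the
#' domain most associated with EEG slowing), skipping domains already at
#' their maximum. Deterministic: the same total always yields the same
#' split, the scores sum to the total and never exceed the domain maxima.
#'
#' @param total integer MMSE total in [0, 30].
#' @return Named integer vector over `ot, op, rg, ac, rc, lg, vc, dm`.
#' @export
allocate_domain_scores <- function(total) {
  if (total < 0 || total > 30 || total != round(total))
    stop("MMSE total must be an integer in [0, 30]", call. = FALSE)
  base <- floor(total * DOMAIN_MAX / 30)
  rem <- total - sum(base)
  i <- 1L
  while (rem > 0) {
    j <- (i - 1L) %% length(DOMAIN_MAX) + 1L
    if (base[j] < DOMAIN_MAX[j]) {
      base[j] <- base[j] + 1L
      rem <- rem - 1L
    }
    i <- i + 1L
  }
  stats::setNames(as.integer(base), names(DOMAIN_MAX))
}

#' Simulate a cohort with EEG-slowing structure
#'
#' Draws demographics, a latent slowing variable correlated with age,
#' per-subject EEG generator parameters, "true" biomarker values (the
#' population-scale MDF/PF/ATR implied by the latent slowing, with small
#' measurement noise), and MMSE totals/domain scores. Raw EEG recordings
#' can be materialised for all subjects (`recordings = TRUE`) or generated
#' later per subject with [cohort_recording()]; the per-subject seeds
#' stored in the table make either route reproducible.
#'
#' @param params a [cohort_sim_params()] object.
#' @param recordings if `TRUE`, also simulate and return the raw EEG of
#'   every subject (memory-heavy for large cohorts).
#' @return A data frame of class `cohort_table` with columns `id`, `sex`
#'   (1 female, 0 male), `age`, `edu`, `mmse_total`, the eight domain
#'   scores, `mdf`, `pf`, `atr`, `stage`, plus the per-subject generator
#'   columns `slowing`, `peak_freq`, `alpha_amp`, `theta_amp`, `eeg_seed`.
#'   When `recordings = TRUE` the list of [eeg_recording()] objects is
#'   attached as attribute `"recordings"`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_sim_params(n_subjects = 50, seed = 1))
#' cor(coh$mdf, coh$mmse_total)
simulate_cohort <- function(params, recordings = FALSE) {
  if (!inherits(params, "cohort_sim_params"))
    params <- do.call(cohort_sim_params, as.list(params))
  p <- params
  with_seed(p$seed, {
    n <- p$n_subjects
    sex <- rbinom(n, 1, p$sex_ratio)
    age <- runif(n, p$age_range[1], p$age_range[2])
    edu <- round(runif(n, p$edu_range[1], p$edu_range[2]))
    # latent slowing: positively age-linked, unit variance
    slowing <- 0.55 * scale(age)[, 1] + sqrt(1 - 0.55^2) * rnorm(n)
    # population-scale biomarkers implied by the latent slowing
    peak_freq <- pmin(12, pmax(5, 8.7 - 1.1 * slowing + rnorm(n, 0, 0.25)))
    mdf <- pmin(12.9, pmax(4.1, 0.75 * peak_freq + 2 - 0.25 * slowing +
                             rnorm(n, 0, 0.15)))
    atr <- exp(log(1.22) - 0.28 * slowing + rnorm(n, 0, 0.10))
    alpha_amp <- 15 * exp(-0.10 * slowing)
    theta_amp <- 6 * exp(0.18 * slowing)
    zs <- function(x) as.numeric(scale(x))
    preds <- cbind(slowing = zs(slowing), mdf = zs(mdf), pf = zs(peak_freq),
                   atr = zs(atr), age = zs(age), edu = zs(edu), sex = sex)
    lin <- p$intercept + rnorm(n, 0, p$noise_sd)
    if (length(p$coeffs))
      lin <- lin + as.numeric(preds[, names(p$coeffs), drop = FALSE] %*% p$coeffs)
    mmse <- pmin(30L, pmax(0L, as.integer(round(lin))))
    dom <- t(vapply(mmse, allocate_domain_scores, integer(8)))
    eeg_seed <- sample.int(.Machine$integer.max - 1L, n)
    coh <- data.frame(id = sprintf("S%04d", seq_len(n)), sex = sex,
                      age = age, edu = edu, mmse_total = mmse)
    coh <- cbind(coh, as.data.frame(dom))
    coh$mdf <- as.numeric(mdf)
    coh$pf <- as.numeric(peak_freq)
    coh$atr <- as.numeric(atr)
    coh$stage <- assign_stage(coh$mmse_total)
    coh$slowing <- as.numeric(slowing)
    coh$peak_freq <- as.numeric(peak_freq)
    coh$alpha_amp <- as.numeric(alpha_amp)
    coh$theta_amp <- as.numeric(theta_amp)
    coh$eeg_seed <- eeg_seed
    class(coh) <- c("cohort_table", "data.frame")
    if (recordings)
      attr(coh, "recordings") <- lapply(seq_len(n), function(i)
        cohort_recording(coh, i, p$eeg_params))
    coh
  })
}

#' Materialise the raw EEG of one cohort subject
#'
#' Rebuilds the subject's recording from the generator columns stored in a
#' [simulate_cohort()] table (peak frequency, component amplitudes and the
#' per-subject seed), so large cohorts can be processed one recording at a
#' time.
#'
#' @param cohort a `cohort_table`.
#' @param i row index of the subject.
#' @param eeg_params baseline [eeg_sim_params()] supplying duration,
#'   sampling rate, noise amplitude and artifact rates.
#' @return An [eeg_recording()].
#' @export
cohort_recording <- function(cohort, i,
                             eeg_params = eeg_sim_params(alpha_linewidth = 0.4)) {
  row <- cohort[i, ]
  pars <- eeg_params
  pars$peak_freq <- min(12, max(5, row$peak_freq))
  pars$alpha_amp <- row$alpha_amp
  pars$theta_amp <- row$theta_amp
  pars$seed <- row$eeg_seed
  rec <- simulate_eeg(pars)
  rec$subject_id <- row$id
  rec
}
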