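#' Pipeline configuration
#'
#' Builds (and validates) the configuration for [run_pipeline()]. Accepts a
#' YAML file path or a named list; unspecified fields take the defaults
#' below. All randomness is controlled by the explicit seeds; there is no
#' hidden global state.
#'
#' @param config named list of overrides, or a YAML file path.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    n_subjects = 150,
    cohort_csv = NULL,          # when set, read instead of simulating
    duration_s = 60,            # per-subject EEG length for simulation
    fs = 250,
    blink_rate = 0, emg_burst_rate = 0,
    alpha_linewidth = 0.4,
    apply_filter = TRUE,
    test_fraction = 0.2, k = 10, n_boot = 1000,
    seeds = list(sim = 11L, split = 12L, folds = 13L, boot = 14L),
    out_dir = "eegslow_out",
    log_level = "info")
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(cfg$cohort_csv) && !file.exists(cfg$cohort_csv))
    stop("cohort_csv does not exist: ", cfg$cohort_csv, call. = FALSE)
  stopifnot(cfg$test_fraction > 0, cfg$test_fraction < 1, cfg$k >= 2)
  structure(cfg, class = c("pipeline_config", "list"))
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message("[eegslow] ", sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: `simulate` (or load a cohort CSV), `extract`
#' (per-subject device filtering, artifact screening and biomarker
#' extraction from the raw EEG), `associate` (Pearson/partial correlations
#' by sex with Fisher/Zou comparisons, marginal-means stage contrasts,
#' standardized MLR), `predict` ([fit_mmse_model()]) and `report`
#' (tabular CSV outputs, final coefficients as JSON, Bland-Altman plot
#' data, and a JSON run manifest with per-file checksums).
#'
#' @param config a [pipeline_config()], a named list, or a YAML path.
#' @param stages subset of stages to run (later stages require earlier
#'   ones in the same call).
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "extract", "associate",
                                    "predict", "report")) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  counts <- list()
  t0 <- Sys.time()
  emit <- function(name, writer) {
    p <- file.path(cfg$out_dir, name)
    writer(p)
    outputs <<- c(outputs, p)
    p
  }

  ## -- simulate / load -------------------------------------------------------
  eeg_pars <- eeg_sim_params(duration_s = cfg$duration_s, fs = cfg$fs,
                             alpha_linewidth = cfg$alpha_linewidth,
                             blink_rate = cfg$blink_rate,
                             emg_burst_rate = cfg$emg_burst_rate)
  if (!is.null(cfg$cohort_csv)) {
    cohort <- read_cohort(cfg$cohort_csv)
    pipe_log(cfg, "loaded cohort: %d subjects", nrow(cohort))
  } else {
    cohort <- simulate_cohort(cohort_sim_params(
      n_subjects = cfg$n_subjects, eeg_params = eeg_pars,
      seed = cfg$seeds$sim))
    pipe_log(cfg, "simulated cohort: %d subjects", nrow(cohort))
  }
  counts$subjects_in <- nrow(cohort)
  if ("simulate" %in% stages)
    emit("cohort.csv", function(p) write_cohort(cohort, p))

  ## -- extract ---------------------------------------------------------------
  if (any(c("extract", "associate", "predict") %in% stages) &&
      is.null(cfg$cohort_csv)) {
    bm <- vector("list", nrow(cohort))
    n_screen_fail <- 0L
    for (i in seq_len(nrow(cohort))) {
      rec <- cohort_recording(cohort, i, eeg_pars)
      if (cfg$apply_filter) rec <- apply_device_filters(rec)
      b <- extract_biomarkers(rec)
      if (!all(b$screen$screen200$pass)) n_screen_fail <- n_screen_fail + 1L
      bm[[i]] <- as.data.frame(b)
    }
    bm <- do.call(rbind, bm)
    cohort$mdf <- bm$mdf; cohort$pf <- bm$pf; cohort$atr <- bm$atr
    counts$screen200_failures <- n_screen_fail
    pipe_log(cfg, "extracted biomarkers: %d subjects, %d screen failures",
             nrow(bm), n_screen_fail)
    if ("extract" %in% stages)
      emit("biomarkers.csv", function(p) write_biomarkers(bm, p))
  }

  ## -- associate -------------------------------------------------------------
  if ("associate" %in% stages) {
    groups <- list(total = rep(TRUE, nrow(cohort)),
                   male = cohort$sex == 0, female = cohort$sex == 1)
    vars <- c("mdf", "pf", "atr")
    rows <- list()
    for (v in vars) for (g in names(groups)) {
      idx <- groups[[g]]
      pr <- pearson_ci(cohort[[v]][idx], cohort$mmse_total[idx],
                       bonferroni_m = length(vars))
      rows[[paste(v, g)]] <- data.frame(
        variable = v, group = g, n = pr$n, estimate = pr$estimate,
        ci_low = pr$ci_low, ci_high = pr$ci_high, p = pr$p)
    }
    cors <- do.call(rbind, rows)
    cmp <- do.call(rbind, lapply(vars, function(v) {
      rM <- cors$estimate[cors$variable == v & cors$group == "male"]
      rF <- cors$estimate[cors$variable == v & cors$group == "female"]
      fz <- fisher_z_independent(rF, sum(groups$female), rM, sum(groups$male))
      data.frame(variable = v, delta_female_minus_male = fz$delta,
                 z = fz$z, p = fz$p, ci_low = fz$ci_low, ci_high = fz$ci_high)
    }))
    emit("associations_pearson.csv", function(p)
      write.csv(cors, p, row.names = FALSE))
    emit("associations_sex_comparison.csv", function(p)
      write.csv(cmp, p, row.names = FALSE))
    ctr <- do.call(rbind, lapply(vars, function(v) {
      cc <- marginal_means_contrasts(cohort, v)
      cbind(variable = v, cc$contrasts)
    }))
    emit("stage_contrasts.csv", function(p)
      write.csv(ctr, p, row.names = FALSE))
    # unadjusted and partial correlations with the MMSE total and domains
    responses <- c("mmse_total", names(DOMAIN_MAX))
    covs <- as.matrix(cohort[, c("sex", "age", "edu")])
    pp <- do.call(rbind, lapply(vars, function(v) do.call(rbind, lapply(
      responses, function(resp) {
        un <- pearson_ci(cohort[[v]], cohort[[resp]],
                         bonferroni_m = length(responses))
        pa <- partial_pearson(cohort[[v]], cohort[[resp]], covs,
                              bonferroni_m = length(responses))
        data.frame(variable = v, response = resp,
                   r = un$estimate, r_lo = un$ci_low, r_hi = un$ci_high,
                   r_p = un$p, partial_r = pa$estimate,
                   partial_lo = pa$ci_low, partial_hi = pa$ci_high,
                   partial_p = pa$p)
      }))))
    emit("domain_correlations.csv", function(p)
      write.csv(pp, p, row.names = FALSE))
    mlr <- do.call(rbind, lapply(vars, function(v) {
      m <- mlr_standardized(cohort, "mmse_total", v)
      data.frame(eeg_var = v, beta = m$beta, beta_lo = m$beta_ci[1],
                 beta_hi = m$beta_ci[2], p = m$p, beta_std = m$beta_std,
                 adj_r2 = m$adj_r2, df = m$df)
    }))
    emit("mlr.csv", function(p) write.csv(mlr, p, row.names = FALSE))
    pipe_log(cfg, "association tables written")
  }

  ## -- predict ---------------------------------------------------------------
  if ("predict" %in% stages) {
    model <- fit_mmse_model(cohort, test_fraction = cfg$test_fraction,
                            k = cfg$k,
                            seeds = list(split = cfg$seeds$split,
                                         folds = cfg$seeds$folds,
                                         boot = cfg$seeds$boot),
                            n_boot = cfg$n_boot)
    tab <- model$cv$family_winners
    tab$test_rmse <- vapply(tab$model, function(m)
      model$evaluations[[m]]$rmse, 1)
    tab$test_r <- vapply(tab$model, function(m)
      model$evaluations[[m]]$pearson$estimate, 1)
    tab$mean_diff <- vapply(tab$model, function(m)
      model$evaluations[[m]]$mean_diff, 1)
    tab$icc <- vapply(tab$model, function(m) model$evaluations[[m]]$icc$icc, 1)
    emit("cv_table.csv", function(p) write.csv(tab, p, row.names = FALSE))
    emit("final_coefficients.json", function(p)
      jsonlite::write_json(as.list(coef(model)), p, auto_unbox = TRUE,
                           digits = NA))
    ba <- model$evaluations[[model$winner]]$bland_altman
    emit("bland_altman.csv", function(p)
      write.csv(ba$plot_data, p, row.names = FALSE))
    counts$train <- nrow(model$split$train)
    counts$test <- nrow(model$split$test)
    pipe_log(cfg, "predictive model: winner %s (test RMSE %.3f)",
             model$winner, model$evaluations[[model$winner]]$rmse)
  }

  ## -- report (manifest) -----------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("eegslow")),
    config = unclass(cfg),
    counts = counts,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log(cfg, "manifest written to %s", file.path(cfg$out_dir, "manifest.json"))
  invisible(manifest)
}
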