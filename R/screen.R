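#' Voltage-threshold artifact screening
#'
#' Reports, per channel, the fraction of samples whose absolute amplitude
#' exceeds a voltage threshold, and whether the channel passes the screen.
#' A channel fails only when the fraction is strictly greater than
#' `max_fraction` (so a fraction exactly at the limit passes). The default
#' 200 microvolt / 10% rule is a common exclusion threshold for serious
#' movement artifact; screening is report-only -- no samples are removed.
#'
#' @param rec an [eeg_recording()].
#' @param threshold_uV absolute-amplitude threshold in microvolts (> 0).
#' @param max_fraction largest acceptable exceedance fraction, in (0, 1].
#' @return A data frame with one row per channel: `channel`, `fraction`,
#'   `pass`, plus the thresholds used as attributes.
#' @export
#' @examples
#' rec <- simulate_eeg(eeg_sim_params(duration_s = 10, seed = 1))
#' screen_artifacts(rec)
screen_artifacts <- function(rec, threshold_uV = 200, max_fraction = 0.10) {
  as_recording_check(rec)
  if (n_samples(rec) == 0) stop("empty signal", call. = FALSE)
  if (threshold_uV <= 0) stop("'threshold_uV' must be > 0", call. = FALSE)
  if (max_fraction <= 0 || max_fraction > 1)
    stop("'max_fraction' must be in (0, 1]", call. = FALSE)
  frac <- colMeans(abs(rec$signals) > threshold_uV)
  out <- data.frame(channel = colnames(rec$signals), fraction = as.numeric(frac),
                    pass = as.numeric(frac) <= max_fraction,
                    row.names = NULL)
  attr(out, "threshold_uV") <- threshold_uV
  attr(out, "max_fraction") <- max_fraction
  out
}

#' Earliest artifact-free one-minute slice
#'
#' Scans for the earliest contiguous window of `slice_s` seconds in which
#' every sample of both channels stays within `bound_uV` microvolts -- the
#' strict low-contamination condition used to check that biomarkers from a
#' clean slice agree with those from the full recording.
#'
#' @param rec an [eeg_recording()] at least `slice_s` seconds long.
#' @param slice_s window length in seconds (default 60).
#' @param bound_uV amplitude bound in microvolts (default 80).
#' @return A list of class `clean_slice`: `found` (logical), and when found
#'   `recording` (the windowed [eeg_recording()]) and `start_s` (window
#'   onset in seconds). `found = FALSE` signals "no clean slice" without
#'   raising an error.
#' @export
select_clean_slice <- function(rec, slice_s = 60, bound_uV = 80) {
  as_recording_check(rec)
  if (rec$duration_s < slice_s)
    stop("recording shorter than the requested slice", call. = FALSE)
  L <- round(slice_s * rec$fs)
  ok <- rowSums(abs(rec$signals) > bound_uV) == 0
  bad_cum <- c(0, cumsum(!ok))
  n <- n_samples(rec)
  starts <- seq_len(n - L + 1L)
  valid <- bad_cum[starts + L] - bad_cum[starts] == 0
  if (!any(valid))
    return(structure(list(found = FALSE, recording = NULL, start_s = NA_real_),
                     class = "clean_slice"))
  s <- which(valid)[1L]
  win <- eeg_recording(rec$signals[s:(s + L - 1L), , drop = FALSE], rec$fs,
                       rec$subject_id)
  structure(list(found = TRUE, recording = win, start_s = (s - 1L) / rec$fs),
            class = "clean_slice")
}

#' @export
print.clean_slice <- function(x, ...) {
  if (x$found)
    cat(sprintf("<clean_slice> found, starts at %.3f s (%.0f s window)\n",
                x$start_s, x$recording$duration_s))
  else cat("<clean_slice> no clean slice\n")
  invisible(x)
}
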