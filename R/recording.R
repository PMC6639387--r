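#' Two-channel prefrontal EEG recording
#'
#' Container for an eyes-closed prefrontal EEG recording: two voltage series
#' in microvolts from the Fp1 (left) and Fp2 (right) sites of the 10/20
#' system, sampled at a common rate.
#'
#' @param signals numeric matrix with one column per channel, in microvolts.
#'   Column names are matched case-insensitively to `Fp1`/`Fp2`; an unnamed
#'   two-column matrix is taken as (Fp1, Fp2) in order.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id identifier attached to the recording.
#' @param events optional data frame logging artifact events
#'   (`type`, `onset_s`, `duration_s`, `amplitude_uV`).
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `signals` (n x 2 matrix, columns `Fp1`, `Fp2`), `fs`, `duration_s`,
#'   `subject_id` and `events`.
#' @export
#' @examples
#' rec <- eeg_recording(cbind(sin(1:500), cos(1:500)), fs = 250)
#' rec$duration_s
eeg_recording <- function(signals, fs, subject_id = NA_character_,
                          events = NULL) {
  if (is.data.frame(signals)) signals <- as.matrix(signals)
  if (!is.matrix(signals) || !is.numeric(signals) || ncol(signals) != 2L)
    stop("'signals' must be a numeric matrix with two channels", call. = FALSE)
  stop_if_not_scalar(fs, "fs")
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  cn <- colnames(signals)
  if (!is.null(cn)) {
    i1 <- grep("fp1", cn, ignore.case = TRUE)
    i2 <- grep("fp2", cn, ignore.case = TRUE)
    if (length(i1) != 1L || length(i2) != 1L)
      stop("channel labels must identify Fp1 and Fp2", call. = FALSE)
    signals <- signals[, c(i1, i2), drop = FALSE]
  }
  colnames(signals) <- c("Fp1", "Fp2")
  structure(list(
    signals = signals,
    fs = fs,
    duration_s = nrow(signals) / fs,
    subject_id = subject_id,
    events = events %||% data.frame(type = character(), onset_s = numeric(),
                                    duration_s = numeric(),
                                    amplitude_uV = numeric())
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: 2 ch (Fp1, Fp2), %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signals), x$fs, x$duration_s))
  if (nrow(x$events)) cat(sprintf("  %d logged artifact event(s)\n", nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$signals)

as_recording_check <- function(rec) {
  if (!inherits(rec, "eeg_recording"))
    stop("expected an 'eeg_recording' object", call. = FALSE)
  if (any(!is.finite(rec$signals)))
    stop("recording contains non-finite samples", call. = FALSE)
  rec
}
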