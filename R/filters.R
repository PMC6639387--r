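#' Acquisition-device digital filter cascade
#'
#' Designs the three IIR Butterworth filters of the recording amplifier:
#' a 2nd-order band-stop with edges 55 and 65 Hz (mains), a 1st-order
#' high-pass with cutoff 2.6 Hz, and an 8th-order low-pass with cutoff
#' 43 Hz. Coefficients are exposed so the transfer function can be
#' inspected.
#'
#' @param fs sampling rate in Hz; must exceed 130 Hz so the 65 Hz stop-band
#'   edge lies below Nyquist.
#' @return A list of class `device_filters` with elements `band_stop`,
#'   `high_pass`, `low_pass` (each a `signal::Arma`-compatible list with
#'   `b`, `a` polynomial coefficients) and `fs`.
#' @export
device_filters <- function(fs) {
  stop_if_not_scalar(fs, "fs")
  if (fs <= 130)
    stop("'fs' must exceed 130 Hz for the 55-65 Hz stop band", call. = FALSE)
  nyq <- fs / 2
  structure(list(
    band_stop = signal::butter(2, c(55, 65) / nyq, type = "stop"),
    high_pass = signal::butter(1, 2.6 / nyq, type = "high"),
    low_pass  = signal::butter(8, 43 / nyq, type = "low"),
    fs = fs
  ), class = "device_filters")
}

#' Apply the device filter cascade to a recording
#'
#' Runs each channel through the band-stop, high-pass and low-pass
#' Butterworth filters of [device_filters()], causally (forward only) by
#' default, as an acquisition device would. Zero-phase (forward-backward)
#' filtering is available but off by default.
#'
#' @param rec an [eeg_recording()].
#' @param zero_phase apply each filter forward and backward
#'   (`signal::filtfilt`) instead of causally.
#' @return The filtered recording.
#' @export
#' @examples
#' rec <- simulate_eeg(eeg_sim_params(duration_s = 5, seed = 1))
#' filtered <- apply_device_filters(rec)
apply_device_filters <- function(rec, zero_phase = FALSE) {
  as_recording_check(rec)
  flt <- device_filters(rec$fs)
  run1 <- function(f, x) {
    if (zero_phase) signal::filtfilt(f, x) else as.numeric(signal::filter(f, x))
  }
  sig <- apply(rec$signals, 2, function(x)
    run1(flt$low_pass, run1(flt$high_pass, run1(flt$band_stop, x))))
  out <- eeg_recording(sig, rec$fs, rec$subject_id, rec$events)
  attr(out, "filters") <- flt
  out
}

#' Magnitude response of the device filter cascade
#'
#' Evaluates |H(f)| of the cascaded band-stop, high-pass and low-pass
#' filters at the requested frequencies.
#'
#' @param flt a [device_filters()] object.
#' @param freqs frequencies in Hz.
#' @return Numeric vector of magnitude gains.
#' @export
filter_gain <- function(flt, freqs) {
  w <- exp(-1i * 2 * pi * freqs / flt$fs)
  h1 <- function(f) {
    num <- vapply(w, function(z) sum(f$b * z^(seq_along(f$b) - 1)), complex(1))
    den <- vapply(w, function(z) sum(f$a * z^(seq_along(f$a) - 1)), complex(1))
    num / den
  }
  Mod(h1(flt$band_stop) * h1(flt$high_pass) * h1(flt$low_pass))
}
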