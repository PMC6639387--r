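# frequency-band conventions: half-open bins so theta and alpha partition
# the dominant band exactly
THETA_BAND <- c(4, 8)
ALPHA_BAND <- c(8, 13)
DOMINANT_BAND <- c(4, 13)

#' Rectangular-window periodogram of a recording
#'
#' Removes the mean of each channel and computes a single full-length
#' discrete Fourier transform (rectangular window, no segment averaging),
#' returning the one-sided spectral power per bin in squared microvolts.
#' The one-sided scaling conserves power: the sum of the power values of a
#' channel equals the mean square of its mean-removed signal (Parseval).
#'
#' @param rec an [eeg_recording()] of at least one second.
#' @return A list of class `power_spectrum`: `freqs` (Hz, from 0 to fs/2),
#'   `power` (bins x 2 matrix, columns `Fp1`, `Fp2`), `resolution`
#'   (`fs/N` Hz), `fs` and `n` (samples per channel).
#' @export
#' @examples
#' rec <- simulate_eeg(eeg_sim_params(duration_s = 10, seed = 1))
#' ps <- compute_periodogram(rec)
#' peak_frequency(ps)
compute_periodogram <- function(rec) {
  as_recording_check(rec)
  n <- n_samples(rec)
  if (n < rec$fs) stop("recording must be at least 1 s long", call. = FALSE)
  half <- floor(n / 2)
  pow <- apply(rec$signals, 2, function(x) {
    x <- x - mean(x)
    p <- Mod(fft(x))^2 / n^2            # two-sided power per bin
    ps <- p[seq_len(half + 1L)]
    # fold negative frequencies onto positive ones; DC has no mirror and,
    # for even n, neither does the Nyquist bin
    mirrored <- if (n %% 2 == 0) seq(2L, half) else seq(2L, half + 1L)
    ps[mirrored] <- 2 * ps[mirrored]
    ps
  })
  structure(list(freqs = (0:half) * rec$fs / n, power = pow,
                 resolution = rec$fs / n, fs = rec$fs, n = n),
            class = "power_spectrum")
}

band_idx <- function(ps, lo, hi) {
  if (lo < 0 || hi <= lo || hi > ps$fs / 2 + ps$resolution / 2)
    stop("invalid band edges", call. = FALSE)
  idx <- which(ps$freqs >= lo & ps$freqs < hi)
  if (!length(idx)) stop("band contains no frequency bins", call. = FALSE)
  idx
}

#' Band power of a spectrum
#'
#' Sums the one-sided spectral power over a half-open frequency band
#' `[lo_Hz, hi_Hz)` and reports both the linear sum (squared microvolts)
#' and its natural logarithm. A zero linear sum yields `log_power = -Inf`.
#'
#' @param ps a [compute_periodogram()] result.
#' @param lo_Hz,hi_Hz band edges in Hz, `0 <= lo < hi <= fs/2`.
#' @param channel channel index or name (1 = Fp1, 2 = Fp2).
#' @return `list(linear_sum =, log_power =)`.
#' @export
band_power <- function(ps, lo_Hz, hi_Hz, channel = 1) {
  idx <- band_idx(ps, lo_Hz, hi_Hz)
  s <- sum(ps$power[idx, channel])
  list(linear_sum = s, log_power = log(s))
}

in_band_power <- function(ps, channel) {
  idx <- band_idx(ps, DOMINANT_BAND[1], DOMINANT_BAND[2])
  list(idx = idx, power = ps$power[idx, channel], freqs = ps$freqs[idx])
}

#' Median frequency (MDF) of the 4-13 Hz band
#'
#' Two-step rule: (1) sum the spectral power over the dominant 4-13 Hz
#' band and halve it; (2) return the frequency of the first bin (ascending)
#' at which the cumulative in-band power strictly exceeds that half-total.
#' A bin that reaches exactly half does not stop the scan.
#'
#' @param ps a [compute_periodogram()] result.
#' @param channel channel index or name.
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(ps, channel = 1) {
  b <- in_band_power(ps, channel)
  tot <- sum(b$power)
  if (tot <= 0) stop("no spectral power in the 4-13 Hz band", call. = FALSE)
  k <- which(cumsum(b$power) > tot / 2)[1L]
  b$freqs[k]
}

#' Peak frequency (PF) of the 4-13 Hz band
#'
#' Frequency of the largest spectral power in the dominant 4-13 Hz band;
#' ties break to the lowest frequency.
#'
#' @inheritParams median_frequency
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(ps, channel = 1) {
  b <- in_band_power(ps, channel)
  if (sum(b$power) <= 0)
    stop("no spectral power in the 4-13 Hz band", call. = FALSE)
  b$freqs[which.max(b$power)]
}

#' Alpha-to-theta power ratio (ATR)
#'
#' Ratio of the alpha-band (8-13 Hz) to theta-band (4-8 Hz) spectral power,
#' computed as the exponential of the difference of the natural-log band
#' powers -- i.e. the linear power ratio, which is unitless.
#'
#' @inheritParams median_frequency
#' @return The ATR (> 0).
#' @export
alpha_theta_ratio <- function(ps, channel = 1) {
  pa <- band_power(ps, ALPHA_BAND[1], ALPHA_BAND[2], channel)
  pt <- band_power(ps, THETA_BAND[1], THETA_BAND[2], channel)
  if (pt$linear_sum <= 0) stop("zero theta-band power", call. = FALSE)
  exp(pa$log_power - pt$log_power)
}

#' Extract the slowing biomarkers of a recording
#'
#' Computes the periodogram of each channel, derives MDF, PF and ATR per
#' channel, and averages the per-channel values arithmetically across Fp1
#' and Fp2 (variables are averaged, not spectra). Voltage screens at 200,
#' 150 and 100 microvolts are attached for reporting; no recording is
#' rejected for artifacts.
#'
#' @param rec an [eeg_recording()].
#' @return A list of class `biomarker_set`: `mdf`, `pf`, `atr`
#'   (channel-averaged), `per_channel` (2-row data frame), and
#'   `screen` (exceedance fractions and pass flags at 200/150/100
#'   microvolts).
#' @export
extract_biomarkers <- function(rec) {
  ps <- compute_periodogram(rec)
  per <- do.call(rbind, lapply(1:2, function(ch) data.frame(
    channel = colnames(rec$signals)[ch],
    mdf = median_frequency(ps, ch),
    pf = peak_frequency(ps, ch),
    atr = alpha_theta_ratio(ps, ch))))
  screen <- lapply(c(screen200 = 200, screen150 = 150, screen100 = 100),
                   function(thr) screen_artifacts(rec, threshold_uV = thr))
  structure(list(mdf = mean(per$mdf), pf = mean(per$pf), atr = mean(per$atr),
                 per_channel = per, screen = screen,
                 subject_id = rec$subject_id),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("<biomarker_set> MDF %.3f Hz, PF %.3f Hz, ATR %.3f\n",
              x$mdf, x$pf, x$atr))
  invisible(x)
}

#' Flatten a biomarker set to a one-row data frame
#'
#' @param x a `biomarker_set`.
#' @return One-row data frame with channel-averaged and per-channel values
#'   plus the 200/150/100 microvolt screen outcomes (worst channel).
#' @export
as.data.frame.biomarker_set <- function(x, ...) {
  data.frame(id = x$subject_id, mdf = x$mdf, pf = x$pf, atr = x$atr,
             mdf_fp1 = x$per_channel$mdf[1], mdf_fp2 = x$per_channel$mdf[2],
             pf_fp1 = x$per_channel$pf[1], pf_fp2 = x$per_channel$pf[2],
             atr_fp1 = x$per_channel$atr[1], atr_fp2 = x$per_channel$atr[2],
             screen200 = all(x$screen$screen200$pass),
             screen150 = all(x$screen$screen150$pass),
             screen100 = all(x$screen$screen100$pass))
}
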