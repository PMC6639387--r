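#' Parameters for the synthetic eyes-closed EEG generator
#'
#' Bundles and validates the signal-model parameters used by
#' [simulate_eeg()]. The model emulates eyes-closed prefrontal EEG: a
#' dominant alpha-range oscillation whose peak sits in the 5-12 Hz band,
#' a theta component, a 1/f ("pink") background, and optional blink and
#' EMG artifact events.
#'
#' @param duration_s recording length in seconds (default 300, i.e. 5 min).
#' @param fs sampling rate in Hz (default 250). Must exceed 86 Hz so the
#'   0-43 Hz analysis band is below Nyquist.
#' @param peak_freq dominant oscillation frequency in Hz, within [5, 12].
#' @param alpha_amp,theta_amp,pink_noise_amp component amplitudes in
#'   microvolts (sinusoid amplitudes for alpha/theta, RMS for the pink
#'   background); all must be >= 0.
#' @param theta_freq frequency of the theta component in Hz (default 6).
#' @param alpha_linewidth spectral full width (Hz) of the dominant
#'   oscillation, produced by phase diffusion. 0 (default) gives a pure
#'   sinusoid whose periodogram peak sits in a single bin; real eyes-closed
#'   alpha peaks are a few tenths of a Hz wide.
#' @param blink_rate,emg_burst_rate artifact event rates in events/min
#'   (default 0: clean recording).
#' @param channel_noise_cor correlation of the pink background between the
#'   Fp1 and Fp2 channels (default 0.8; oscillatory components are fully
#'   shared, mimicking near-duplicate prefrontal sites).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#'
#' @return A list of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(duration_s = 300, fs = 250, peak_freq = 10,
                           alpha_amp = 15, theta_amp = 6,
                           pink_noise_amp = 10, theta_freq = 6,
                           alpha_linewidth = 0,
                           blink_rate = 0, emg_burst_rate = 0,
                           channel_noise_cor = 0.8, seed = NULL) {
  if (alpha_linewidth < 0) stop("'alpha_linewidth' must be >= 0", call. = FALSE)
  stop_if_not_scalar(duration_s, "duration_s")
  stop_if_not_scalar(fs, "fs")
  if (duration_s <= 0) stop("'duration_s' must be positive", call. = FALSE)
  if (fs <= 2 * 43) stop("'fs' must exceed 86 Hz (twice the 43 Hz analysis edge)",
                         call. = FALSE)
  if (peak_freq < 5 || peak_freq > 12)
    stop("'peak_freq' must lie in [5, 12] Hz", call. = FALSE)
  for (a in c(alpha_amp = alpha_amp, theta_amp = theta_amp,
              pink_noise_amp = pink_noise_amp))
    if (a < 0) stop("amplitudes must be >= 0", call. = FALSE)
  if (blink_rate < 0 || emg_burst_rate < 0)
    stop("artifact rates must be >= 0", call. = FALSE)
  structure(list(duration_s = duration_s, fs = fs, peak_freq = peak_freq,
                 alpha_amp = alpha_amp, theta_amp = theta_amp,
                 pink_noise_amp = pink_noise_amp, theta_freq = theta_freq,
                 alpha_linewidth = alpha_linewidth,
                 blink_rate = blink_rate, emg_burst_rate = emg_burst_rate,
                 channel_noise_cor = channel_noise_cor, seed = seed),
            class = "eeg_sim_params")
}

# 1/f background by spectral shaping of white Gaussian noise. The shaping
# gain is 1/sqrt(max(f, 1 Hz)) so the power spectrum falls as 1/f above
# 1 Hz (the tested 4-40 Hz range) while variance stays bounded at DC.
pink_noise <- function(n, fs, rms_amp) {
  if (rms_amp == 0) return(numeric(n))
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  gain <- 1 / sqrt(pmax(f, 1))
  gain[1] <- 0                              # remove DC
  x <- Re(fft(spec * gain, inverse = TRUE)) / n
  x * rms_amp / rms(x)
}

#' Simulate a two-channel eyes-closed prefrontal EEG recording
#'
#' Generates Fp1/Fp2 voltage series as the sum of a dominant oscillation at
#' `peak_freq` (with slow random amplitude modulation and a random phase),
#' a theta component, and a pink (1/f) background. The oscillations are
#' shared between channels; the backgrounds of the two channels are
#' correlated copies (shared source plus independent noise). Artifact
#' events are added through [inject_artifacts()] when the rates are
#' positive.
#'
#' @param params an [eeg_sim_params()] object.
#' @return An [eeg_recording()] with the generator's event log attached.
#' @export
#' @examples
#' rec <- simulate_eeg(eeg_sim_params(duration_s = 10, seed = 1))
#' extract_biomarkers(rec)$pf
simulate_eeg <- function(params) {
  if (!inherits(params, "eeg_sim_params"))
    params <- do.call(eeg_sim_params, as.list(params))
  p <- params
  with_seed(p$seed, {
    n <- round(p$duration_s * p$fs)
    t <- (seq_len(n) - 1) / p$fs
    # slow sinusoidal amplitude modulation (~10% depth) with random phase
    env <- 1 + 0.1 * sin(2 * pi * runif(1, 0.05, 0.15) * t + runif(1, 0, 2 * pi))
    # phase diffusion broadens the spectral line to ~alpha_linewidth Hz
    jitter <- if (p$alpha_linewidth > 0)
      cumsum(rnorm(n, 0, sqrt(2 * pi * p$alpha_linewidth / p$fs))) else 0
    alpha <- p$alpha_amp * env *
      sin(2 * pi * p$peak_freq * t + jitter + runif(1, 0, 2 * pi))
    theta <- p$theta_amp * sin(2 * pi * p$theta_freq * t + runif(1, 0, 2 * pi))
    shared <- pink_noise(n, p$fs, p$pink_noise_amp)
    rho <- p$channel_noise_cor
    mix <- function() sqrt(rho) * shared + sqrt(1 - rho) * pink_noise(n, p$fs, p$pink_noise_amp)
    sig <- cbind(Fp1 = alpha + theta + mix(), Fp2 = alpha + theta + mix())
    rec <- eeg_recording(sig, p$fs)
    if (p$blink_rate > 0 || p$emg_burst_rate > 0)
      rec <- inject_artifacts(rec, p$blink_rate, p$emg_burst_rate, seed = NULL)
    rec
  })
}

# tapered cosine (Tukey) window, taper fraction a
tukey_window <- function(n, a = 0.3) {
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < a / 2
  hi <- x > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / a + 1)))
  w
}

#' Add blink and EMG artifact events to a recording
#'
#' Blinks are transient high-amplitude deflections (0.2-0.5 s, 100-400
#' microvolts, tapered-rectangular shape, near-identical on both prefrontal
#' channels). EMG events are broadband 20-43 Hz bursts (0.2-1 s). Event
#' counts are Poisson with the given rates; a log of every injected event
#' is kept on the returned copy.
#'
#' @param rec an [eeg_recording()].
#' @param blink_rate,emg_burst_rate event rates in events per minute (>= 0).
#' @param seed integer seed or `NULL`.
#' @return A modified copy of `rec` with `events` extended.
#' @export
inject_artifacts <- function(rec, blink_rate = 2, emg_burst_rate = 1,
                             seed = NULL) {
  as_recording_check(rec)
  if (blink_rate < 0 || emg_burst_rate < 0)
    stop("artifact rates must be >= 0", call. = FALSE)
  if (blink_rate == 0 && emg_burst_rate == 0) return(rec)
  with_seed(seed, {
    n <- n_samples(rec); fs <- rec$fs
    minutes <- rec$duration_s / 60
    ev <- list()
    add_event <- function(type, onset, dur, amp) {
      ev[[length(ev) + 1L]] <<- data.frame(type = type, onset_s = onset,
                                           duration_s = dur, amplitude_uV = amp)
    }
    sig <- rec$signals
    n_blink <- stats::rpois(1, blink_rate * minutes)
    for (i in seq_len(n_blink)) {
      dur <- runif(1, 0.2, 0.5)
      amp <- runif(1, 100, 400)
      onset <- runif(1, 0, max(rec$duration_s - dur, 0))
      idx <- round(onset * fs) + seq_len(round(dur * fs))
      idx <- idx[idx >= 1 & idx <= n]
      pulse <- amp * tukey_window(length(idx))
      sig[idx, 1] <- sig[idx, 1] + pulse
      sig[idx, 2] <- sig[idx, 2] + 0.95 * pulse
      add_event("blink", onset, dur, amp)
    }
    n_emg <- stats::rpois(1, emg_burst_rate * minutes)
    if (n_emg > 0) {
      bp <- signal::butter(4, c(20, 43) / (fs / 2), type = "pass")
      for (i in seq_len(n_emg)) {
        dur <- runif(1, 0.2, 1)
        amp <- runif(1, 20, 60)            # burst RMS in microvolts
        onset <- runif(1, 0, max(rec$duration_s - dur, 0))
        idx <- round(onset * fs) + seq_len(round(dur * fs))
        idx <- idx[idx >= 1 & idx <= n]
        for (ch in 1:2) {
          burst <- as.numeric(signal::filter(bp, rnorm(length(idx))))
          burst <- burst / max(rms(burst), .Machine$double.eps) * amp *
            tukey_window(length(idx), 0.5)
          sig[idx, ch] <- sig[idx, ch] + burst
        }
        add_event("emg", onset, dur, amp)
      }
    }
    events <- rbind(rec$events, do.call(rbind, ev))
    eeg_recording(sig, fs, rec$subject_id, events = events)
  })
}
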