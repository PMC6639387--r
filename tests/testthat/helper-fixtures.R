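# fixtures built in code; no stored data

# a power_spectrum object with arbitrary bin powers (single channel copied
# to both), for direct unit tests of the band statistics
make_spectrum <- function(freqs, power) {
  stopifnot(length(freqs) == length(power))
  structure(list(freqs = freqs, power = cbind(Fp1 = power, Fp2 = power),
                 resolution = freqs[2] - freqs[1],
                 fs = 2 * max(freqs), n = 2 * (length(freqs) - 1)),
            class = "power_spectrum")
}

# brute-force median-frequency oracle: linear scan of the cumulative sum
mdf_oracle <- function(freqs, power, lo = 4, hi = 13) {
  idx <- which(freqs >= lo & freqs < hi)
  p <- power[idx]
  half <- sum(p) / 2
  cum <- 0
  for (i in seq_along(p)) {
    cum <- cum + p[i]
    if (cum > half) return(freqs[idx][i])
  }
  NA_real_
}

# pure-tone recording, same or different frequency per channel
tone_recording <- function(freq, duration_s = 60, fs = 250, amp = 1,
                           freq2 = freq) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  eeg_recording(cbind(Fp1 = amp * sin(2 * pi * freq * t),
                      Fp2 = amp * sin(2 * pi * freq2 * t)), fs = fs)
}

# cohort with exact stage sizes (for split and degrees-of-freedom checks)
cohort_with_stages <- function(n_t3, n_t2, n_t1, seed = 1) {
  withr::with_seed(seed, {
    n <- n_t3 + n_t2 + n_t1
    mmse <- c(sample(28:30, n_t3, TRUE), sample(25:27, n_t2, TRUE),
              sample(5:24, n_t1, TRUE))
    d <- data.frame(id = sprintf("S%04d", 1:n),
                    sex = rbinom(n, 1, 0.5),
                    age = runif(n, 50, 90), edu = round(runif(n, 0, 18)),
                    mmse_total = mmse,
                    mdf = runif(n, 5, 11), pf = runif(n, 5, 12),
                    atr = runif(n, 0.5, 2.5))
    d$stage <- assign_stage(d$mmse_total)
    d
  })
}
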