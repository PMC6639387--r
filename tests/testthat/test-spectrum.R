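test_that("a pure sinusoid concentrates its analytic power in one bin", {
  rec <- tone_recording(10, duration_s = 300, fs = 250)
  ps <- compute_periodogram(rec)
  total <- sum(ps$power[, 1])
  expect_equal(total, 0.5, tolerance = 1e-6)       # A^2/2 for unit amplitude
  bin10 <- which(ps$freqs == 10)
  expect_length(bin10, 1)
  expect_gt(ps$power[bin10, 1] / total, 0.99)
  expect_equal(ps$resolution, 1 / 300)
})

test_that("Parseval holds: one-sided power sums to the mean square", {
  set.seed(42)
  for (n_s in c(4, 10)) {
    sig <- cbind(Fp1 = rnorm(250 * n_s, sd = 3), Fp2 = rnorm(250 * n_s, sd = 3))
    rec <- eeg_recording(sig, fs = 250)
    ps <- compute_periodogram(rec)
    for (ch in 1:2) {
      x <- sig[, ch] - mean(sig[, ch])
      expect_equal(sum(ps$power[, ch]), mean(x^2), tolerance = 1e-10)
    }
  }
  # odd sample count exercises the other folding branch
  rec <- eeg_recording(cbind(Fp1 = rnorm(251 * 3), Fp2 = rnorm(251 * 3)),
                       fs = 251)
  ps <- compute_periodogram(rec)
  x <- rec$signals[, 1] - mean(rec$signals[, 1])
  expect_equal(sum(ps$power[, 1]), mean(x^2), tolerance = 1e-10)
})

test_that("periodogram rejects bad input", {
  expect_error(compute_periodogram(eeg_recording(cbind(rnorm(100), rnorm(100)),
                                                 fs = 250)), "1 s")
  sig <- cbind(rnorm(500), rnorm(500)); sig[5, 1] <- NA
  expect_error(eeg_recording(sig, 250) |> compute_periodogram(),
               "non-finite")
})

test_that("band_power sums half-open bands and flat spectra split 4:5", {
  freqs <- seq(0, 40, by = 0.5)
  ps <- make_spectrum(freqs, rep(1, length(freqs)))
  theta <- band_power(ps, 4, 8)
  alpha <- band_power(ps, 8, 13)
  expect_equal(theta$linear_sum, 8)    # bins 4, 4.5, ..., 7.5
  expect_equal(alpha$linear_sum, 10)   # bins 8, 8.5, ..., 12.5
  expect_equal(alpha$linear_sum / theta$linear_sum, 5 / 4)
  expect_equal(theta$log_power, log(8))
  # all power at 10 Hz: band sum equals total
  p2 <- rep(0, length(freqs)); p2[freqs == 10] <- 3.3
  ps2 <- make_spectrum(freqs, p2)
  expect_equal(band_power(ps2, 8, 13)$linear_sum, 3.3)
  expect_identical(band_power(ps2, 4, 8)$log_power, -Inf)
  expect_error(band_power(ps, 13, 8), "invalid band")
  expect_error(band_power(ps, 39.9, 39.95), "no frequency bins")
})

test_that("median frequency follows the strict first-exceed rule", {
  freqs <- seq(0, 125, by = 0.25)
  pt <- function(at, val = 1) {
    p <- rep(0, length(freqs)); p[match(at, freqs)] <- val; p
  }
  expect_equal(median_frequency(make_spectrum(freqs, pt(10))), 10)
  # two equal point masses: the 5 Hz bin reaches exactly half, does not
  # strictly exceed it, so the scan continues to 11 Hz
  expect_equal(median_frequency(make_spectrum(freqs, pt(c(5, 11)))), 11)
  # flat in-band spectrum: first bin past the midpoint of [4, 13)
  flat <- make_spectrum(freqs, rep(1, length(freqs)))
  expect_lt(abs(median_frequency(flat) - 8.5), 2 * flat$resolution)
  expect_error(median_frequency(make_spectrum(freqs, pt(20))), "no spectral power")
})

test_that("median frequency matches the brute-force oracle exactly", {
  set.seed(7)
  for (i in 1:100) {
    res <- sample(c(0.1, 0.25, 1 / 3, 0.5), 1)
    freqs <- seq(0, 40, by = res)
    power <- rexp(length(freqs))
    ps <- make_spectrum(freqs, power)
    expect_identical(median_frequency(ps), mdf_oracle(freqs, power))
  }
})

test_that("MDF sits at the cumulative half-power crossing", {
  set.seed(8)
  freqs <- seq(0, 40, by = 0.2)
  for (i in 1:20) {
    power <- rexp(length(freqs))
    ps <- make_spectrum(freqs, power)
    mdf <- median_frequency(ps)
    idx <- which(freqs >= 4 & freqs < 13)
    cum <- cumsum(power[idx])
    half <- sum(power[idx]) / 2
    k <- match(mdf, freqs[idx])
    expect_gt(cum[k], half)
    if (k > 1) expect_lte(cum[k - 1], half)
    expect_gte(mdf, 4); expect_lt(mdf, 13)
  }
})

test_that("peak frequency takes the in-band argmax, ties to the lower bin", {
  freqs <- seq(0, 40, by = 0.5)
  p <- rep(0, length(freqs)); p[freqs == 9] <- 2
  expect_equal(peak_frequency(make_spectrum(freqs, p)), 9)
  p2 <- rep(0, length(freqs)); p2[freqs %in% c(6, 10)] <- 1
  expect_equal(peak_frequency(make_spectrum(freqs, p2)), 6)
})

test_that("biomarkers are invariant to overall spectral scale", {
  set.seed(9)
  freqs <- seq(0, 40, by = 0.25)
  power <- rexp(length(freqs))
  a <- make_spectrum(freqs, power)
  b <- make_spectrum(freqs, power * 137.5)
  expect_identical(median_frequency(a), median_frequency(b))
  expect_identical(peak_frequency(a), peak_frequency(b))
  expect_equal(alpha_theta_ratio(a), alpha_theta_ratio(b), tolerance = 1e-12)
})

test_that("the alpha-theta ratio is the linear band-power ratio", {
  freqs <- seq(0, 40, by = 0.5)
  p <- rep(0, length(freqs))
  p[freqs == 6] <- 2; p[freqs == 10] <- 2          # equal band powers
  expect_equal(alpha_theta_ratio(make_spectrum(freqs, p)), 1)
  flat <- make_spectrum(freqs, rep(1, length(freqs)))
  expect_equal(alpha_theta_ratio(flat), 5 / 4)
  tone <- rep(1e-9, length(freqs)); tone[freqs == 10] <- 1
  expect_gt(alpha_theta_ratio(make_spectrum(freqs, tone)), 100)
  ptheta0 <- rep(0, length(freqs)); ptheta0[freqs == 10] <- 1
  expect_error(alpha_theta_ratio(make_spectrum(freqs, ptheta0)), "theta")
})

test_that("extract_biomarkers averages variables across channels", {
  rec <- tone_recording(10, duration_s = 30)
  b <- extract_biomarkers(rec)
  expect_equal(b$mdf, b$per_channel$mdf[1])        # identical channels
  expect_equal(b$pf, 10)
  rec2 <- tone_recording(9, duration_s = 30, freq2 = 11)
  b2 <- extract_biomarkers(rec2)
  expect_equal(b2$per_channel$pf, c(9, 11))
  expect_equal(b2$pf, 10)                          # mean of variables
  d <- as.data.frame(b2)
  expect_true(d$screen200 && d$screen100)
})

test_that("biomarkers of simulated subjects respect their ranges", {
  coh <- simulate_cohort(cohort_sim_params(n_subjects = 25, seed = 3))
  for (i in seq_len(10)) {
    rec <- cohort_recording(coh, i, eeg_sim_params(duration_s = 20))
    b <- extract_biomarkers(rec)
    expect_gte(b$mdf, 4); expect_lte(b$mdf, 13)
    expect_gte(b$pf, 4); expect_lte(b$pf, 13)
    expect_gt(b$atr, 0)
  }
})
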