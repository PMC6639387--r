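---
title: "Methods: prefrontal EEG slowing biomarkers and MMSE prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prefrontal EEG slowing biomarkers and MMSE prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegslow)
```

## Scope and assumptions

`eegslow` analyses two-channel (Fp1, Fp2), eyes-closed, resting-state EEG
sampled at 250 Hz for five minutes per subject, in microvolts. The working
assumptions are those of quantitative resting-EEG work in elderly cohorts:
the dominant intrinsic oscillation lies in the 4–13 Hz band; cognitive
decline expresses itself as *slowing* — a shift of spectral mass from alpha
(8–13 Hz) toward theta (4–8 Hz); and the recording is approximately
stationary over the five minutes, so a single full-length spectrum is a
meaningful summary. Subjects sit relaxed with eyes closed; artifact
contamination is screened and reported but recordings are not rejected or
cleaned, matching a protocol in which an operator supervises data quality
at acquisition time.

## Spectral estimation and the three biomarkers

The spectrum is a single full-length periodogram: per channel the mean is
removed, an unwindowed (rectangular) FFT is taken, and one-sided power per
bin is formed so that the bin powers sum exactly to the mean square of the
mean-removed signal. Parseval conservation is enforced in the tests at
1e-8 relative error. No Welch segmentation or tapering is applied: at 300 s
the 1/300 Hz resolution is far finer than the structures of interest and
variance of the spectral estimate is immaterial for band sums, while
segmentation would blur the peak location that two of the three biomarkers
depend on.

Band conventions are half-open: theta = [4, 8) Hz, alpha = [8, 13) Hz,
dominant band = [4, 13) Hz. This makes theta and alpha an exact partition
of the dominant band; with closed intervals the 8 Hz bin would be counted
twice.

* **MDF** — the cumulative in-band power is scanned in ascending frequency
  and the median frequency is the first bin *strictly* exceeding half the
  in-band total. The strict rule is observable: a spectrum with equal point
  masses at 5 and 11 Hz has MDF 11 Hz, because the 5 Hz bin reaches exactly
  half without exceeding it. A brute-force cumulative-sum oracle replicates
  the implementation exactly on random spectra in the test suite.
* **PF** — the in-band argmax; ties break to the lowest frequency, which is
  deterministic and conservative in the direction of slowing.
* **ATR** — band powers are summed linearly and reported on the natural-log
  scale; the ratio is `exp(ln Pα − ln Pθ)`, i.e. the linear power ratio.
  A ratio of log powers was rejected because its value would depend on the
  power unit (µV² vs mV² changes both logs additively), whereas a power
  *ratio* is unitless with a plausible range around 1; the logs are kept in
  `band_power()` for reporting.

Per-channel values are averaged arithmetically across Fp1 and Fp2
(variables are averaged, never spectra), after which a subject contributes
one MDF, PF and ATR.

`apply_device_filters()` reproduces an acquisition amplifier: 2nd-order
Butterworth band-stop (55–65 Hz), 1st-order high-pass (2.6 Hz), 8th-order
low-pass (43 Hz), cascaded and applied causally (forward-only), since they
model a real-time device. Zero-phase filtering is available
(`zero_phase = TRUE`) but off by default; it would be anachronistic for
device emulation and affects none of the band statistics materially.

Artifact screening reports the fraction of samples exceeding 200 µV (also
150 and 100 µV), failing a channel only when the fraction strictly exceeds
10%. It is report-only: no data are rejected. `select_clean_slice()`
implements the complementary stability check — the earliest one-minute
window with every sample within ±80 µV — so that biomarkers from the clean
slice can be compared against the full recording with a paired t test.

## The synthetic generator

The generator exists because the analysis needs raw-data-shaped input with
known ground truth. Per subject the EEG is: a dominant oscillation at
`peak_freq` (5–12 Hz) with ~10% slow amplitude modulation and optional
phase-diffusion linewidth; a 6 Hz theta sinusoid; and a 1/f background
synthesized by spectral shaping of white Gaussian noise (gain
`1/sqrt(max(f, 1))`, giving an exact −1 log-log slope over the tested
4–40 Hz range with bounded low-frequency variance). Oscillations are fully
shared between channels; backgrounds are correlated copies (shared +
independent pink noise, correlation 0.8), reflecting how close Fp1 and Fp2
are physiologically. Blinks are 0.2–0.5 s tapered pulses of 100–400 µV on
both channels; EMG events are 20–43 Hz band-passed bursts. Default artifact
rates are zero, so a default recording always passes the 200 µV/10% screen.

The default `alpha_linewidth` is 0 in `eeg_sim_params()` — a pure tone,
which keeps the single-tone identities exact (PF recovers the injected
frequency to within one bin whenever the oscillation-to-background power
ratio in band is ≥ 2). Cohort emulation instead uses a 0.4 Hz linewidth:
with a literal sinusoid the entire oscillation occupies one bin, making MDF
and PF *identical* for every subject and the predictive design exactly
collinear. Real eyes-closed alpha peaks are a few tenths of a Hz wide; the
finite linewidth is what separates the median from the peak frequency, as
in real data.

Cohorts are driven by one latent slowing scalar per subject, unit variance,
correlated 0.55 with age. It maps linearly to the per-subject peak
frequency (8.7 − 1.1·slowing Hz), to the alpha/theta amplitude balance and,
with small measurement noise, to the tabulated "true" MDF/PF/ATR columns.
MMSE is a rounded, [0, 30]-clipped linear combination of standardized
predictors plus Gaussian noise; the default coefficients
(slowing −2.2, age −1.0, edu +1.1 MMSE points per SD; intercept 25; noise
SD 2.7) were chosen once to produce a community-elderly-like distribution —
mean near 25, SD near 4, roughly balanced stage tertiles and moderate
negative age and positive education correlations — and are not fitted to
any dataset. Domain scores are allocated proportionally to the printed
domain maxima (5, 5, 3, 5, 3, 6, 1, 2) with remaining points handed out in
a fixed priority order beginning with orientation to time, the domain most
associated with slowing; the rule is deterministic, sums exactly to the
total and respects each maximum.

What the generator does *not* emulate: non-Gaussian and non-stationary
backgrounds, drowsiness drift, eyes-open segments, realistic MMSE item
response processes, or floor/ceiling psychometrics beyond hard clipping.
Passing tests therefore demonstrate correctness of the *procedures* under a
controlled data-generating process, not clinical performance on real
cohorts.

## Association statistics

Stage assignment uses fixed cut points (T3: 28–30; T2: 25–27; T1: ≤ 24),
not data-driven tertiles. The stage analysis fits a Gaussian identity-link
linear model `biomarker ~ sex * stage + age + edu` (8 parameters, so the
contrast df is n − 8), computes estimated marginal means per sex × stage
cell with age and education at their whole-sample means (the standard
estimated-marginal-means convention; per-sex covariate means were the other
defensible reading and are obtainable via `emmeans` directly), and tests
the consecutive contrasts T2 − T3 and T1 − T2 within sex. The four
contrasts form one Bonferroni family: adjusted p-values are `min(1, 4p)`
and the simultaneous intervals use level 1 − α/4. `emmeans` provides the
marginal-means machinery; an independent normal-equations oracle in the
test suite confirms estimates, standard errors and t statistics to 1e-8.

Correlation machinery: Pearson correlations carry Fisher-transform
confidence intervals and t-based p-values; partial correlations are
correlations of residuals after regressing both variables on the
covariates, with degrees of freedom reduced accordingly. Two independent
correlations are compared with the Fisher Z test plus Zou's
modified-asymptotic interval for the difference; two dependent correlations
sharing a variable use the Meng–Rosenthal–Rubin Z. Meng's statistic and
interval live on the Fisher-z scale, so `delta` for that method is the
difference of the transformed correlations (the raw difference is reported
alongside); this keeps the estimate inside its own interval by
construction. Monte-Carlo calibration in the acceptance tests checks the
type-I error of both tests at 0.05 ± 0.01 (5,000 null replicates, n = 200)
and Zou coverage at 95% ± 1% (10,000 replicates).

ICC is the two-way absolute-agreement single-measure form, ICC(A,1),
computed from the mean squares of the subjects × raters layout. Absolute
agreement was chosen over consistency because both uses of the ICC here —
interchangeability of recording sites and agreement between observed and
model-predicted MMSE — are claims about values matching, not merely
co-varying; a constant offset should (and does) lower the index. The
bootstrap CI resamples subjects with replacement, percentile method,
1,000 replicates under a fixed seed. Bland–Altman limits are
mean ± 1.96 SD of differences with approximate CIs (standard error
`sqrt(3 s²/n)` for the limits).

## Predictive modelling

The design uses the five continuous predictors (MDF, PF, ATR, age,
education) standardized with training-set means and SDs only — test rows
are transformed with training parameters, never their own, to keep
information from leaking across the split. Each standardized predictor X
contributes X, X², sex:X and sex:X²; with the sex main effect this is 21
columns plus an unpenalized intercept. The sex-specific published equations
are the male/female evaluations of this single interacted model, which is
why some coefficients are shared between the sexes (interaction terms
zeroed out by the penalty) and others differ.

"Weighted least squares" is implemented as least squares with unit weights
and an exposed `weights` argument, since no weighting scheme is specified
for the method; the AIC stepwise search (both directions, from the full
model) provides the reduced variant, and both are cross-validated.

The elastic-net objective is
`(1/2n)·RSS + λ[α‖β‖₁ + (1−α)‖β‖₂²/2]` with the intercept unpenalized and
no internal rescaling of columns (the design is standardized upstream, and
coefficients are reported on that scale). The 1/(2n) scaling makes λ values
in the 1e-3–1e-2 range the interesting region for MMSE-scale responses.
Fitting is delegated to `glmnet` with one adjustment: `glmnet` internally
standardizes the gaussian response by its 1/n-SD, which leaves the L1
penalty on the requested scale but shrinks the effective L2 penalty by that
SD. Requesting `λ' = λ(α + (1−α)·sd(y))` at mixing `α' = αλ/λ'` makes
`glmnet` solve exactly the objective above; the tests verify the ridge
closed form `(XᵀX/n + λI)⁻¹Xᵀy/n` to 1e-6 on random problems, the LASSO
λ_max = max|Xᵀ(y − ȳ)|/n deactivation threshold, equality with ordinary
least squares at λ = 0, and the subgradient (KKT) conditions to 1e-6 across
the (α, λ) grid. Single-(α, λ) fits are computed along a short warm-start
path ending exactly at the requested λ.

The hyperparameter grid is 300 log-spaced λ from 10 down to 1e-4 and
α ∈ {0, 0.1, …, 1} — 3,300 penalized candidates. Validation is
stage-stratified 10-fold cross-validation on the training 80%; a
candidate's score is the mean over folds of the per-fold RMSE, and winners
are reported per family (WLS, ridge at α = 0, elastic net at 0 < α < 1,
LASSO at α = 1) and overall. The 80/20 split is stratified by stage with
per-stratum proportional allocation and largest-remainder rounding toward
`round(0.2 n)` (at the reference cohort's stage sizes this yields a
99-subject test set; exact per-stratum rounding conventions are not
identifiable from a printed 80/20 description, and ±1 subject is
immaterial). Split, fold and bootstrap seeds are independent configuration
keys. The held-out 20% is touched exactly once, after selection; a test
verifies that perturbing the held-out rows cannot change the
cross-validation table.

Predicted MMSE is left unclipped by default (differences beyond the [0, 30]
range are informative in Bland–Altman displays); `clip_predictions = TRUE`
is available.

`predict_final_equation()` evaluates the published sex-specific final
LASSO polynomials as fixed coefficient tables; it is the reference point
for exactness tests and expects standardized inputs. `roc_auc()` supplies
the rank-statistic AUC (ties counted half) and accuracy at the
Youden-optimal threshold for stage dichotomisation (T1 vs T2∪T3).

## Numerical choices and degenerate inputs

- Zero in-band power is an error for MDF/PF; zero theta power is an error
  for ATR; a zero band sum in `band_power()` returns `log_power = -Inf`
  rather than an error, so callers can distinguish "no power" from
  "invalid band".
- Non-finite samples, empty signals, reversed band edges, degenerate
  ranges, constant columns and rank-deficient designs raise immediate
  errors with plain messages.
- "No clean slice" is an explicit result object, not an exception: it is an
  expected outcome on contaminated recordings.
- The EDF writer quantizes to the 16-bit grid over a symmetric physical
  range; round-trips agree within half a quantization step. The CSV dialect
  writes 17 significant digits so text round-trips are bit-exact.
- All stochastic functions take explicit seeds and restore the caller's RNG
  state; fixed seeds give bit-identical outputs.

## Problem sizes in the test suite

The suite exercises the statistics at the sizes at which their properties
are informative while keeping a default run short: calibration of the
correlation-comparison tests uses 5,000 null replicates at n = 200 and
10,000 coverage replicates at n = 100 per group; solver oracles use 50
random problems; full-pipeline parameter recovery runs 50 replicates of an
n = 500 cohort with noise SD 2.7 and true effects on MDF, age and
education, requiring the selected model's test RMSE to sit within 15% of
the noise floor and its support to contain the true terms in at least 90%
of replicates. Degrees-of-freedom checks run at n = 496 with stage sizes
162/179/155.

## Known limitations

Single full-record periodograms are high-variance estimates per bin; the
biomarkers are robust to this (band sums and dominant peaks), but
bin-level values should not be interpreted individually. The generator's
latent-slowing mechanism is deliberately minimal — one scalar cannot
reproduce dissociations between biomarkers that real pathology may produce.
The MLR and marginal-means models assume Gaussian errors for an integer,
ceiling-limited response; this mirrors the reference analysis but is an
approximation, and the prediction stage partially absorbs it through the
rounding/clipping in the generator. Meng's interval is reported on the
Fisher-z scale, which is not directly comparable to a raw correlation
difference when correlations are large. The CLI and pipeline are thin
orchestration layers; computational claims are all tested at the function
level.
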