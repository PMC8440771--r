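---
title: "Models and methods behind drowsydrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drowsydrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowsydrive)
```

# The scientific question

When a driver stops driving and merely supervises a self-driving vehicle,
the task demands drop while the obligation to stay alert does not. The
analyses in this package quantify whether that passive supervision unmasks
latent sleepiness, using paired drives per participant (one manually
controlled, one self-driving, order counterbalanced in blocks of four) and
four families of outcome:

* **slow rolling eye movements (SREMs)** — out-of-phase slow deflections in
  the bilateral EOG lasting at least 0.5 s, a physiological signature of
  the wake-to-sleep transition: event counts and time to first event;
* **subjective sleepiness** — Karolinska Sleepiness Scale (KSS) ratings,
  a 9-point ordinal scale, after each drive;
* **vigilant attention** — a 5-minute psychomotor vigilance task (PVT):
  mean reaction time (adjusted for the 82 ms device latency) and lapses
  (adjusted RT strictly above 500 ms);
* **neural synchronization** — band-specific co-fluctuation of EEG power
  envelopes across the four midline electrodes (Fz, Cz, Pz, Oz), measured
  with the binarized derivative method (BDM).

No public dataset accompanies the design, so the package ships a
ground-truth-annotated synthetic cohort generator; every downstream stage
is validated against that ground truth.

# The synthetic cohort

`cohort_config()` fixes the study conditions; `generate_cohort()` draws a
cohort; `generate_eeg_eog()` and `generate_behavioral()` synthesize each
session. The defaults encode the published study scale wherever the
papers' summary statistics pin it down:

* habitual sleep duration ~ Normal(5.9 h, 0.9 h), the actigraphic cohort
  mean, truncated to 3–10 h;
* SREM counts: Poisson with rate
  $\lambda_{ij} = m\,e^{\beta\,\text{self}_j + b\,(s_i - \bar s)} u_i$,
  where $m = 5$ events per 48-min manual drive, the condition log rate
  ratio $\beta = 1.06$ (the ratio of the published condition means),
  the per-hour sleep slope $b = -0.48$, and a subject-level gamma frailty
  $u_i$ with shape $k = 0.85$ shared by both drives. Marginally the
  counts are negative binomial with variance $m + m^2/k$; the frailty
  also induces the within-subject correlation the repeated-measures
  models must absorb. The dispersion pools the $k$ implied by all four
  printed condition-level mean/SD pairs (0.57–1.29). The sleep slope is
  applied in both conditions; the published manual-condition slopes
  straddle zero, so a shared slope is the simplest faithful choice.
* KSS: a latent-normal model (base 5.2, 0.8 × a latent sleepiness trait,
  +1.5 for the self-driving drive, residual SD 1.8) thresholded to 1–9;
  total SD ≈ 2, matching the printed SDs.
* PVT: trial RTs are a shifted lognormal body (shift 150 ms; body
  mean 273 ms manual / 294 ms self-driving on the latency-adjusted scale,
  trial SD 65 ms — the design's power calculation assumed 300 ± 65 ms)
  mixed with a lapse tail (500 ms + Exponential(mean 120 ms)) at
  per-trial probability 0.014 / 0.037, i.e. the published mean lapse
  counts over ~45 trials. A stable per-subject speed offset (SD 30 ms)
  carries the between-subject variance.

## Signals

Each scalp channel is a sum over the five canonical bands (delta 1–3,
theta 4–7, alpha 8–12, beta 13–25, gamma 26–40 Hz) of a sinusoidal
carrier at the band center, amplitude-modulated by a nonnegative envelope
(low-pass-filtered rectified Gaussian noise, bandwidth 0.8 Hz, mean 1),
plus white noise (3 µV). The envelope of channel $c$ in band $b$ is the
mixture $w_b\,\text{shared}_b + (1-w_b)\,\text{private}_{cb}$: the
coupling weight $w_b$ is exactly the quantity the BDM estimates, which is
what makes the generator a usable oracle. Per-band amplitudes follow a
1/f-like profile (12, 8, 10, 5, 3 µV). The envelope bandwidth matters:
envelopes much slower than ~0.5 Hz change so little between samples that
any spectral leakage dominates the derivative's sign, and coupling
becomes invisible to the BDM; 0.8 Hz also matches the amplitude-
modulation timescales of real band-limited EEG better than a slower
choice would.

EOG channels carry slow conjugate background activity (6 µV, partly
shared between the eyes), in-phase biexponential blinks (180–300 µV,
~0.35 s, at 5 per minute — the rate that reproduces the published ~16%
artifact-excision fraction), and anti-phase half-sine SREM deflections
(EOG-R = −0.9 × EOG-L, 35–60 µV, 1–3 s) at the ground-truth onsets.
Blinks are drawn at least 1 s away from SREM intervals: blinking is
suppressed while the eyes roll at sleep onset, and the separation keeps
the artifact mask from swallowing genuine SREMs. Mastoids are
low-amplitude noise.

What the generator does **not** emulate: realistic sleep-stage EEG
(spindles, K-complexes, 1/f broadband structure), eyelid dynamics,
nonstationary drowsiness drift within a drive, or muscle/movement
artifacts. Passing tests therefore certify the pipeline's statistical
machinery and its behavior under the modeled signal features — not
performance on real polysomnography.

# Preprocessing

`rereference()` subtracts the averaged mastoids (A1, A2) from every
channel. `filter_chain()` applies a zero-phase Butterworth chain:
high-pass 0.4823 Hz (the cutoff equivalent to a 0.33 s amplifier time
constant), order 2 (12 dB/octave); low-pass 70 Hz, order 4
(24 dB/octave); optional 60 Hz notch. At reduced sampling rates the
low-pass and notch must be re-specified below Nyquist
(`filter_spec(lowpass_hz = 45, notch_hz = NULL)` for the compressed
profiles used in the tests).

`detect_ocular_artifacts()` thresholds the magnitude of the product of
the two EOG traces at mean + 3 SD of the absolute product (the only
reading of "three standard deviations of the mean of the product" that
yields a scalar threshold) and excises the 2 s centered on every
suprathreshold sample. The product is computed per session, after
re-referencing and filtering. On cohorts at the default artifact rate
this removes ~12–16% of the data, matching the published ~16.5%.
`apply_mask()` splits the recording into clean contiguous segments
(default minimum 2 s, the shortest stretch supporting a 1 Hz band edge);
discarded short stretches count as excluded, so retained + excluded time
always reconstructs the recording to one sample.

# SREM detection

The scoring definition — out-of-phase rolling deflections ≥ 0.5 s in both
EOG channels — is automated as a dual-threshold (hysteresis) rule on the
slow-filtered (0.1–1.5 Hz) pair:

1. **Background scale.** Robust SD = bias-corrected lower decile of the
   per-second RMS profile. A global MAD breaks down once events and their
   filter ringing occupy a large fraction of the trace; the quietest
   tenth of one-second blocks stays background-dominated at any
   realistic density. The decile of block RMS underestimates the SD
   (a 1-s block of a 1.4 Hz-wide process has ~4 degrees of freedom), so
   it is divided by the matching chi-square decile factor.
2. **Core.** Samples where both slow-trace Hilbert envelopes exceed
   4 × background SD while the 0.5 s sliding-window Pearson correlation
   of the traces is ≤ −0.5; a candidate needs a core run of ≥ 0.25 s.
   The envelope (not the rectified trace) carries the amplitude
   criterion, so a single rolling deflection is not fragmented at the
   zero crossings the band-pass introduces.
3. **Extent.** Each core is extended while both envelopes hold
   2 × background SD; events closer than 0.5 s merge (band-pass ringing
   splits one movement); each merged event is then trimmed to the span
   where the traces hold the larger of the floor and 30% of the event's
   own peak, which strips ringing tails; events shorter than 0.5 s are
   dropped.
4. **Vetoes.** An event must be slow-dominated (≥ 50% of its 0.1–10 Hz
   power inside the slow band) — this rejects brief high-amplitude
   jerks whose envelope smear would otherwise satisfy the duration rule
   at any amplitude — and its anti-phase envelope peak must lie outside
   the artifact mask. Judging mask exclusion at the peak, rather than by
   overlap, keeps genuine deflections whose smeared flanks touch a
   neighboring blink's window.

In-phase deflections (blinks) fail the correlation test at any amplitude.
The published work gives no amplitude criterion (events were scored
visually), so the defaults are calibrated purely on synthetic cohorts: at
the default signal-to-noise they give pooled recall ≈ 0.95 and precision
≈ 1.0 against ground truth. `time_to_first_srem()` turns the event list
into a survival record, censoring event-free drives at the scheduled (or
prematurely terminated) drive end.

# Spectral analysis and the BDM

`welch_psd()` is the standard averaged modified periodogram: Hamming
windows (default 4 s, 50% overlap), one-sided density scaling in
µV²/Hz, windows pooled across clean segments with equal weight per
window (hence duration weighting), then channel-averaged. Parseval
closure (integrated PSD ≈ variance) is enforced in the tests at 5%.

`bdm_synchrony()` implements the band-specific binarized derivative
method: band-pass each channel (order-2 Butterworth, zero-phase), take
the power envelope as the squared magnitude of the analytic signal,
first-difference it at the sampling interval, binarize the derivative
with a signum (ties, a measure-zero event, map to +1), and average the
per-sample cross-channel agreement $|\sum_c s_c|/C$ over time. The
normalization makes synchrony live in [0, 1]: 1 means every channel's
power rises and falls together at every sample, and four independent
channels give the analytic baseline $E|\sum_4 \pm 1|/4 = 0.375$.
Whether the original method averages the signed or the absolute sum is
ambiguous in the source descriptions; the absolute-value reading is
implemented because it yields the bounded, symmetric quantity the
figures describe. Squaring the envelope is monotone, so the sign pattern
— hence the synchrony — is identical for amplitude and power envelopes.

Filtering never crosses artifact-excised gaps: each contiguous segment is
processed independently with a 1 s filter-edge guard. For short,
blink-chopped recordings this per-segment route wastes most of the data
in guards, so the pipeline (`run_study()`) uses
`bdm_synchrony_masked()`: one frequency-domain analytic band-pass over
the whole recording, after which masked samples (plus a 0.5 s margin)
are excised from the derivative-sign stream. On clean data the two
routes agree; on finely chopped data the continuous route is the less
noisy estimator.

# Behavioral summaries

`summarize_pvt()` subtracts the 82 ms system latency from every raw RT,
reports the mean adjusted RT, and counts lapses with a strict
inequality (adjusted RT > 500 ms; 500 exactly is not a lapse).
`summarize_sleep()` sums minutes classified as sleep inside each day's
main rest interval plus naps credited to that day, averaging over the
14-day diary (with a warning when days are missing). The wrist-actigraph
vendor's sleep/wake classifier is deliberately not re-implemented:
synthetic epochs arrive pre-classified, and the classifier's thresholds
travel as metadata. `estimate_rest_interval_fallback()` reproduces the
diary-fallback rule: bedtime = first epoch with activity < 150 while
classified asleep; waketime = first later epoch with activity > 150
while active.

# The statistical battery

* **SREM counts and PVT lapses** — `nb_repeated_condition()`: marginal
  negative-binomial regression on condition with subject-cluster-robust
  (sandwich) standard errors, the independence-working-correlation GEE
  estimator. The p value uses a t reference with G − 1 degrees of
  freedom (G subjects), the standard small-sample correction for
  cluster-robust tests; without it the nominal 5% test rejects ~7% of
  nulls at G = 50. When the NB likelihood degenerates the model falls
  back to Poisson with the same robust inference — the marginal mean
  model, which is all the robust Wald test needs, is unchanged.
* **Counts vs habitual sleep** — `nb_sleep_slope()`: per-condition NB
  regression of counts on sleep hours, reporting the per-hour log slope
  with its model-based CI.
* **Time to first SREM** — `paired_logrank()`: log-rank statistic
  stratified by subject, which conditions out between-subject
  correlation; falls back to the unstratified test (with a warning) when
  every stratum is uninformative.
* **KSS** — `wilcoxon_signed_rank()`: zero differences dropped, V = sum
  of positive-difference ranks, exact p for ≤ 25 informative pairs
  without ties, tie-corrected normal approximation otherwise.
* **PVT mean RT and synchrony** — `mixed_random_intercept()`: REML fit
  of `value ~ condition + (1 | subject)` with Satterthwaite degrees of
  freedom. On balanced complete data this reproduces the paired t-test
  exactly; a singular fit (zero between-subject variance) falls back to
  the paired t-test with a warning. A single random intercept makes the
  "unstructured covariance" of the original description a scalar
  variance.
* **Effect sizes** — `hedges_g_adj()`: standardized mean difference with
  SD pooled as the equal-weight root mean square of the two condition
  SDs and the small-sample correction
  $(N-3)/(N-2.25)\sqrt{(N-2)/N}$, N = paired participants in that
  comparison. This convention reproduces all seven recomputable
  published values at two decimals (half-up rounding). The published
  Study 1 lapse effect (0.58) is not recoverable from its printed
  moments with N = 9 under this (or any pooled-SD) convention we tried;
  it is reported by `printed_study_moments()` consumers as out of scope
  rather than guessed at.
* **Design** — `sample_size_mean_change()`: the normal-approximation
  sample size $\lceil (z_{1-\alpha/2}+z_{power})^2 \sigma^2/\delta^2
  \rceil$, which gives 14 participants for a 50 ms change with SD 65 ms
  at 80% power and α = 0.05.

No multiplicity correction is applied anywhere (none was applied in the
original analyses); α = 0.05 throughout.

# Orchestration and reproducibility

`run_study()` composes the full pipeline per session — simulate,
re-reference, filter, mask, detect, survival records, per-band
synchrony, behavioral summaries — and then runs the battery per
endpoint, returning tidy `sessions`, `tests`, and `synchrony` tables
plus metadata (seed, config hash). Everything derives from the single
config seed: per-subject and per-session sub-seeds are drawn once at
cohort generation, so identical configs give byte-identical reports and
written tables (`write_study_report()` prefixes each file with the seed
and config hash). `verify_printed_effect_sizes()` recomputes the seven
published effect sizes from the embedded printed moments and checks
agreement at two decimals.

## Problem sizes used in the tests

The published session length (48 min at 500 Hz) is a research choice,
not an algorithmic one, so validation runs on time-compressed profiles
chosen for statistical adequacy:

* **moment recovery**: 10,000 subjects (counts only, no signals);
* **detector fidelity**: 6 subjects × 600 s at 125 Hz, with the manual
  SREM mean scaled to 2 per drive so that events-per-minute — the
  quantity the detector's background estimator cares about — stays at
  the study's level. Scaling counts instead of density would pack a
  48-min drive's events into minutes and produce physiologically
  impossible occupancy.
* **calibration**: 1000 null replicates (type-I error of the NB and
  log-rank tests), 300 replicates for CI coverage;
* **direction recovery**: 100 replicates of 16 subjects × 180 s at
  100 Hz (delta band scored), with all effect sizes at their default,
  publication-calibrated levels. Sixteen subjects is the smallest cohort
  for which every endpoint's per-replicate success probability clears
  ~99%, so that the ≥ 95% / 100-replicate requirement is a test of
  direction, not of luck.
* `ci_config()` (8 subjects × 8 min at 250 Hz) is the profile intended
  for interactive end-to-end runs.

# Numerical choices and degenerate inputs

* Zero-phase filtering uses the classic forward-backward algorithm with
  zero padding, applied through `stats::filter`'s compiled loops; the
  Butterworth coefficients come from the `signal` package.
* The Hilbert transform is the standard frequency-domain construction;
  `signum(0)` maps to +1 (deterministic tie-break, measure-zero for
  continuous data).
* Constant EOG product → empty mask with a warning; mask covering
  everything → empty segment set with a warning; all-censored survival
  input and all-zero paired differences are errors, not silent results.
* Robust variances that come out as tiny negative numbers (numerically
  singular meat matrices) are clamped to zero, and a zero standard error
  with a zero estimate yields χ² = 0 rather than NaN.
* Rounding for comparisons against printed values is half-up at two
  decimals, matching how the published tables were typeset.

# Known limitations

* The detector's absolute amplitude thresholds are validated only on
  synthetic data; real EOG would require recalibration of the
  background model (and possibly of the slow-dominance veto) against
  scored recordings.
* BDM synchrony on sinusoid-carrier synthetic data is an easier problem
  than on broadband EEG; absolute synchrony levels here should not be
  compared with published figure axes, only the analytic baselines and
  the coupling ordering are meaningful.
* The generator's SREM rate is homogeneous in time; the published work
  does not report within-drive rate profiles, so an increasing hazard
  (drowsiness accumulating over the drive) is not modeled.
* Premature-termination censoring is supported in the survival records
  but the generator does not simulate terminations; censored records in
  the tests are constructed explicitly.
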