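---
title: "Detecting pulmonary congestion from chest-wall vibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pulmonary congestion from chest-wall vibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pulmonary congestion — fluid accumulation in the lungs — is the principal
driver of heart-failure decompensation and hospitalization. Contact-free
vibrometry measures micro-vibrations of the chest wall; the resulting
single-channel signal carries the S1/S2 heart-sound transients, the slow
respiration wave, and, in congested patients, additional low-frequency energy
concentrated in the inspiratory phase. `lungvib` implements a complete,
testable analysis chain for such signals:

1. simulate cohorts of labeled subjects with physiologically structured
   signals (so the chain is testable without proprietary device data);
2. detect heart-sound and respiratory-phase landmarks;
3. compute landmark-sectioned time and spectrogram features;
4. train a decision-stump AdaBoost classifier with a calibrated inconclusive
   zone; and
5. evaluate diagnostic accuracy with subject-grouped cross-validation and
   bootstrap confidence intervals.

## The signal model

A synthetic measurement is

$$x(t) = h(t)\,\bigl(1 + m\,r(t)\bigr) + g\,r(t) + c(t) + u(t) + v(t) + \varepsilon(t)$$

with the components:

* **Heartbeat train** $h(t)$: Gabor-like damped-sinusoid wavelets at each S1
  onset and, a fixed systolic fraction of the RR interval later, at S2.
  RR intervals are $60/\mathrm{HR}$ with Gaussian beat-to-beat jitter.
  The wavelet envelope SD is 10 ms (about 70 ms total support), matching the
  duration of valve-closure transients; this length also keeps the spectral
  peak of the wavelet at its nominal center frequency (a much shorter wavelet
  lets the negative-frequency lobe pull the periodogram peak upward by
  several Hz). Defaults: 70 bpm &plusmn; 5 bpm, systolic fraction 0.35,
  S1 at 25 Hz (amplitude 1), S2 at 45 Hz (amplitude 0.6).
* **Respiration** $r(t)$: a piecewise-sinusoidal cycle rising from &minus;1
  to +1 over the inhale fraction of the period and falling back during
  exhalation. Defaults: 15 breaths/min, inhale fraction 0.4. It both
  amplitude-modulates the heart sounds (depth $m = 0.25$) and appears
  directly with gain $g = 0.5$.
* **Congestion term** $c(t)$ (cases only): how congestion manifests in the
  measured vibration is not publicly documented, so the generator makes an
  explicit modeling choice: band-limited Gaussian noise in a configurable
  band (default 2–4 Hz) gated to the inhale intervals, plus sparse ~15 ms
  crackle-like transients at a Poisson rate per inhalation. Both amplitudes
  scale with `congestion_effect` &times; `noise_sd`, so the effect size is
  expressed relative to the measurement noise floor and
  `congestion_effect = 0` makes case and control signal distributions
  identical by construction.
* **Nuisance acoustics**: a systolic band-noise murmur (20–60 Hz) for
  subjects with a valvular disorder and an expiratory 30 Hz wheeze tone for
  subjects with a respiratory condition. Their *amplitudes and prevalences*
  are label-independent by default (40% and 15% of subjects respectively):
  if the acoustically active conditions were more common among cases, a
  zero-effect cohort would no longer be a true null and covariate screens
  would not be expected to be flat. A case/control shift in these rates
  remains available through `covariate_config()` for sensitivity analyses.
  Non-acoustic covariates (age, BMI, sex, heart-failure history) do carry a
  case shift, emulating the usual cohort imbalances without touching the
  signal.
* **Noise** $\varepsilon(t)$: white Gaussian, SD 0.05 (1/20 of the S1 peak
  amplitude), a realistic floor for a well-aimed vibrometric measurement.

Defaults are 120 s recordings at 500 Hz. Every measurement draws from an RNG
stream derived by hashing `(seed, subject_id, measurement_id)`, so a single
measurement can be regenerated bit-identically without replaying the cohort.

## Landmark detection

Recordings are cut into overlapping 60 s buffers stepped by 30 s (all full
length; the count is `floor((duration - buffer)/step) + 1`).

**Heart sounds.** The buffer is high-passed at 15 Hz (4th-order Butterworth,
applied forward–backward so landmark times are not lag-shifted), the
amplitude envelope is the magnitude of the analytic signal smoothed over
20 ms, and peaks above 3&times; the median envelope with a 200 ms refractory
period are marked. Peaks are paired into (S1, S2) by the
alternating-interval rule: inter-peak gaps alternate systole (short) and
diastole (long), so a gap below the midpoint of the lower and upper gap
quartiles is systolic; the peak opening it is S1. The rule is applied
per-gap rather than globally so one missed peak cannot flip the labeling of
the rest of the buffer. Fewer than four peaks flags the buffer low-quality
(empty landmarks, no error), the software analog of an unusable measurement.

**Respiratory phases.** The demeaned buffer is low-passed at 1 Hz; extrema
of the result with at least 1 s separation and a small amplitude floor
(10% of the filtered signal's SD) delimit trough&rarr;peak inhale and
peak&rarr;trough exhale intervals. Demeaning first matters: zero-phase
filtering of a DC offset produces edge transients that would otherwise look
like respiration. Note one intrinsic bias: a 1 Hz low-pass keeps only ~4
harmonics of a 0.25 Hz breath, so the extrema of a strongly asymmetric
respiration wave shift slightly toward symmetry, biasing the *detected*
inhale/exhale duration ratio toward 1. The feature is still monotone in the
true asymmetry, which is what the classifier consumes.

All cutoffs, the threshold factor and the refractory period are exposed in
`pipeline_config()`; none are sacred.

## Features

Per buffer, from the detected landmarks:

* **Time features**: mean/SD of S1&rarr;S2, S2&rarr;next-S1 and RR
  intervals; mean/SD envelope amplitude at S1 and S2; S2/S1 amplitude
  ratio; RR coefficient of variation; heart rate; respiratory rate;
  inhale/exhale duration ratio. An SD over fewer than two observations is
  defined as 0 so vectors stay complete.
* **Spectrogram features**: a Hann-window short-time power spectrogram (2 s
  windows, 75% overlap, scaled so summed power equals windowed-signal
  energy) is sectioned vertically into octave bands
  (0.5–1, 1–2, 2–4, 4–8, 8–16, 16–32, 32–64 Hz) and horizontally into
  inhale / exhale / full phases; each cell stores the mean power of its
  cross-section, and each band adds an inhale/exhale energy ratio. The 2–4 Hz
  inhale cell is where the default congestion signature lives.

This yields 43 well-defined features per buffer — deliberately far fewer
than the "thousands" a proprietary device pipeline might generate; the
sectioning construction, not any specific feature list, is the reproducible
object. A measurement's feature vector is the mean of its quality-passing
buffers (median available by config); measurements with no usable buffer are
excluded and reported. Missing cells are imputed with *training-fold* column
medians inside cross-validation, never with information from held-out data,
and imputation never changes a non-missing value.

## Classifier

Classic discrete AdaBoost over decision stumps, T = 50 rounds by default:

* a stump predicts `polarity` where `x > threshold`; fitting scans all
  features, all midpoints of adjacent sorted unique values plus the two
  constant stumps, and both polarities, minimizing weighted error with ties
  broken toward the lower feature index then lower threshold;
* $\alpha_t = \tfrac12 \ln\bigl((1-\varepsilon_t)/\max(\varepsilon_t,
  10^{-10})\bigr)$, multiplicative weight update, renormalization; training
  stops at $\varepsilon_t \ge 0.5$ or (after accepting a capped round)
  $\varepsilon_t = 0$;
* the score is the affine margin map
  $s = \bigl(\sum_t \alpha_t h_t(x) / \sum_t \alpha_t + 1\bigr)/2 \in [0,1]$,
  read as the likelihood that the measurement is congested.

AdaBoost serves as both feature selector and final classifier. With T = 50
the ensemble touches at most 50 unique features — "a few tens". Using one
model avoids inventing an unspecified second stage; this is an
interpretation, recorded here deliberately.

**Operating point and inconclusive zone.** The threshold &theta; maximizes
balanced accuracy over all candidate thresholds (midpoints of adjacent
unique scores plus 0 and 1), ties resolved toward 0.5; `score >= theta`
means *case*. Around &theta; an open inconclusive zone
$(\theta - w, \theta + w)$ is calibrated on training scores: $w$ is the
largest grid value (0 to 0.25 by 0.005) such that at most 5% of calibration
scores fall inside *and* the balanced accuracy on the remaining conclusive
scores is no worse than with no zone. The second condition resolves a
genuine ambiguity — the widest zone meeting the 5% bound alone can sit
asymmetrically on one class and *reduce* conclusive balanced accuracy; both
stated properties of the calibration then hold by construction. Scores
inside the zone are returned as `inconclusive` rather than forced calls.

## Evaluation

* **Grouped 10-fold cross-validation**: subjects are shuffled by seed and
  dealt round-robin, so fold sizes differ by at most one (227 subjects give
  the expected 23/22 split) and repeated measurements of one subject never
  straddle train and test. All imputation, operating-point selection and
  NA calibration happen inside the training folds.
* **Metrics**: sensitivity, specificity, balanced accuracy, trapezoid-rule
  AUC (identical to the Mann–Whitney U probability), predictive values both
  from raw confusion counts at the sample prevalence and via Bayes' identity
  at an external prevalence (default 32%, the expected rate among
  heart-failure patients at routine follow-up), and the likelihood ratios
  PLR = Se/(1&minus;Sp), NLR = (1&minus;Se)/Sp.
* **Inconclusive policy**: `exclude` (default) removes NA outputs from the
  counts; `count_as_error` charges an inconclusive case as a false negative
  and an inconclusive control as a false positive — the pessimistic reading
  under which including inconclusives can only depress specificity and
  sensitivity.
* **Bootstrap**: 95% percentile intervals from 1000 resamples drawn at the
  *subject* level (all of a subject's measurements travel together),
  respecting the repeated-measurement clustering; resampling individual
  measurements would understate the interval width.
* **Duration sweep**: each measurement is cropped to its first 30, 35, …,
  120 s; features, cross-validation and the operating point are recomputed
  per duration (buffers shrink to the cropped length when shorter than
  60 s), yielding a 19-row table of metrics versus measurement duration.
* **Covariate screen**: conclusive predictions are marked
  correct/misclassified; binary covariates are tested with Fisher's exact
  test (two-sided hypergeometric enumeration; the reported odds ratio is the
  sample `ad/bc`), continuous ones with the two-sample Kolmogorov–Smirnov
  test (exact D, asymptotic p). No multiple-testing correction is applied —
  a deliberate choice to keep the screen conservative about declaring
  "no effect" (corrections would only make null results easier).

## What the synthetic cohorts do and do not establish

The generator produces stationary, artifact-free signals with a *known*
congestion signature in a known band. Passing recovery tests therefore shows
that the chain — landmarks, sectioned features, boosting, grouped CV — can
detect an inhale-phase band-energy effect of the configured size without
subject leakage, and that with a zero effect it finds nothing. It does not
validate the clinical premise that real congestion produces this signature,
nor robustness to motion artifacts, arrhythmia, talking, or sensor aiming —
real-device questions outside the scope of a simulation-backed pipeline.

Problem sizes used by the shipped test suite, chosen to exercise the study
conditions at desk scale: recovery and NA-calibration runs on a 100-subject
cohort (effect 3), the null run on 60 subjects (effect 0), the duration
sweep on 40 subjects, all at the full 120 s / 500 Hz defaults with ~1.2
measurements per subject.

## Numerical conventions

* Zero-phase (forward–backward) filtering everywhere a landmark time is
  extracted; the effective attenuation is that of the filter applied twice.
* Degenerate inputs are flagged, not thrown: empty landmark sets produce
  `quality_ok = FALSE` feature vectors; unusable measurements are excluded
  and named in the run summary.
* `score >= theta` is a case; the NA zone is an open interval; with a
  zero-width zone a score exactly at &theta; is a case.
* Bootstrap resamples on which a statistic is undefined are dropped; more
  than 20% undefined marks the interval as failed rather than silently
  narrowing it.
* All randomness flows from explicit seeds: cohort covariates from the
  cohort seed, each measurement from its hashed stream, fold assignment and
  bootstrap from the pipeline seed. Identical seeds reproduce results
  bit-identically.
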