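---
title: "Forecasting seizure risk from multiday cycles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting seizure risk from multiday cycles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclecast)
```

## The problem

People with epilepsy often show *multidien* rhythms: the probability of a
seizure waxes and wanes with cycles of roughly a day, a week, a fortnight or
a month, visible both in the seizure times themselves and in physiological
signals such as heart rate recorded by an ordinary smartwatch. If those
cycles can be detected, phased, and projected forward, the phase of each
cycle at a future hour carries information about seizure likelihood at that
hour — enough to maintain a rolling 60-day risk forecast from nothing more
than a wearable and a diary app.

`cyclecast` implements that pipeline end to end: cycle detection, phase
estimation, phase-binned likelihood models, cycle projection, walk-forward
(pseudo-prospective) forecast issuance, and forecast evaluation, together
with a synthetic-data generator that plants known cycles so every stage can
be validated against ground truth.

## The model, stage by stage

### Heart-rate cycles

Heart rate is represented on a uniform 5-minute grid. Device non-wear gaps
are filled with a constant — the mean heart rate of the training window —
which leaves cycle detection essentially unchanged while being trivially
reproducible (`fill_missing()`).

Cycle periods are found with a continuous Morlet wavelet transform
(nondimensional frequency $\omega_0 = 6$) of the gap-filled signal. We use
24 voices per octave, scales from 2 hours up to half the record length, and
the *global* (time-averaged) wavelet power spectrum. A period counts as a
cycle when the global spectrum has a local maximum exceeding a time-averaged
significance level against a theoretical AR(1) red-noise background, at 95%
confidence by default; the AR(1) coefficient is the lag-1 autocorrelation of
the gap-filled series, and the time-averaged test uses the standard
chi-squared approximation with $\nu = 2\sqrt{1 + (N\,\delta t / \gamma
s)^2}$ degrees of freedom ($\gamma = 2.32$ for the Morlet). The half-record
cap means longer cycles become admissible as recordings grow.

Each detected cycle is extracted with a zero-phase (forward–backward)
second-order Butterworth bandpass whose bandwidth is 30% of the central
frequency — symmetric in the period domain, so an 8-day cycle gets a
5.6–10.4-day passband. The instantaneous phase is the angle of the analytic
signal (Hilbert transform), subsampled to the hourly forecast grid.

### Seizure cycles

Diary cycles use fixed sinusoids rather than filtered signals: candidate
periods run from 1 to 70 days in 0.5-day steps (again capped at half the
training span), the phase of an event at time $t$ for period $P$ is
$2\pi(t - t_0)/P$ wrapped to $(-\pi, \pi]$ with $t_0$ the start of the
training record, and phase locking is measured with the synchronization
index

$$\mathrm{SI} = \left|\frac{1}{N}\sum_{n=1}^N e^{i\theta_n}\right|,$$

the modulus of the circular mean of unit phasors at the event phases.
Periods with $\mathrm{SI} \ge 0.3$ ("moderate" clustering) are retained.
Because strong locking at period $P$ also raises the SI of neighbouring and
harmonically related candidates, we keep the *local maxima* of the SI curve
among qualifying periods rather than every qualifying period. The same SI
criterion is applied to detected heart-rate cycles: a heart-rate rhythm only
enters the forecast if the training seizures are phase-locked to it.

### Phase-binned likelihoods and combination

For each retained cycle the phase interval $(-\pi, \pi]$ is split into 18
equal bins. The seizure likelihood of bin $b$ is the number of seizure
hours whose cycle phase fell in $b$ divided by the number of hours bin $b$
presented in the training record; an hour with several reported events
counts once. Likelihoods from several cycles (and from the two data
modalities) are combined with a logit rule — the geometric mean of odds,

$$p = \prod_i \left(\frac{p_i}{1-p_i}\right)^{1/n}, \qquad
  p_s = \frac{p}{1+p},$$

which is order-invariant, idempotent for equal inputs and monotone in each
argument. Inputs are clipped to $[10^{-4}, 1-10^{-4}]$ first: empty bins
would otherwise contribute zero odds and always-hit bins infinite odds,
a case the likelihood definition leaves open.

Two risk thresholds split the combined likelihood into low, medium and high
risk. They are fitted by grid search over the deduplicated percentiles of
the training likelihood series under two ordering criteria: (1) seizures in
high > seizures in medium > seizures in low; (2) time in low > time in
high. Criterion 2 is optimised after criterion 1 (maximising time-low minus
time-high among pairs satisfying criterion 1, ties preferring less time in
high); when no pair satisfies criterion 1 strictly the ordering is relaxed
to non-strict and flagged, and a constant likelihood series yields
degenerate all-low thresholds with a warning.

### Projection

Seizure cycles are fixed sinusoids, so their future phase is exact.
Heart-rate cycles are projected with an additive time-series model

$$y_t = g_t + s_t + \varepsilon_t,$$

where $g_t$ is a piecewise-linear trend (25 changepoint candidates over the
first 80% of the record) and $s_t$ is a sum of Fourier blocks
$\sum_n a_n \cos(2\pi n t/P) + b_n \sin(2\pi n t/P)$, one per period:
daily, weekly and yearly terms by default plus every detected heart-rate
cycle. Holiday terms are deliberately absent. The fit is penalised least
squares on the hourly-downsampled series (ridge penalties on changepoint
slope adjustments and seasonal coefficients); this native backend keeps the
model family of the popular additive forecasting tools without the
dependency. Fourier order is 3 per daily/multidien term and 10 for the
yearly term. When a detected period nearly coincides with a default
(within 10% in log ratio), the default is dropped — near-duplicate Fourier
blocks are collinear and would split the cycle's amplitude between beating
terms, corrupting the projected phase.

The projected phase of a heart-rate cycle is computed by evaluating the
cycle's seasonal block over the past-plus-future hourly grid, bandpassing
it at the cycle's own band and applying the same Hilbert phase used for
observed data. This keeps the training and projection phase conventions
identical — the alternative (phases straight from the Fourier coefficients)
would introduce a systematic offset against the filtered-signal phases the
bin likelihoods were trained on. The evaluation grid extends two band-high
periods past the horizon so the returned segment is free of Hilbert edge
distortion.

### Walk-forward forecasting

Forecasting starts at the *initial cut-off*: midnight (UTC) ending the day
of the 10th reported seizure. At each issue time the models are refitted on
all data before it and a 60-day hourly forecast segment is issued;
forecasts are reissued at midnight after every reported seizure or 7 days
after the last issue, whichever comes first. The concatenation of segments
— each hour served by the most recent issue at or before it — forms the
pseudo-prospective series, with per-hour provenance retained so causality
is mechanically checkable. Training seizures are excluded from the
evaluation labels. Cycles that drop below the SI threshold at a retraining
simply leave the model.

Hourly forecasts are averaged over each complete calendar day to give the
daily-resolution forecast.

### Evaluation

The ROC here is the *time-in-warning* curve: time spent at or above a
warning threshold against the fraction of seizure hours at or above it, as
the threshold sweeps the forecast values; the AUC is its trapezoidal area
with (0,0) and (1,1) included. The operating point at the fitted
thresholds gives sensitivity and time-in-high. The Brier skill score
compares the forecast's mean squared probability error with a constant
reference at the evaluation-period event rate. Significance uses a
surrogate test: event steps are relocated uniformly at random (without
replacement, 200 shuffles), the AUC recomputed each time, and the forecast
declared above chance when the observed AUC exceeds the 95th percentile of
the surrogate distribution; the p-value uses the add-one permutation
convention so it is never exactly zero. A time-of-day baseline (clock-hour
event profile of the training data, repeating every 24 h) is provided for
comparison; averaged to daily resolution it is constant, i.e. chance.

When several modalities are run, `select_best()` picks the one with the
highest evaluation AUC, ties preferring fewer modalities (diary, then
heart rate, then combined).

## The synthetic-data generator

`scenario_config()` describes a simulated participant. Defaults emulate a
typical wearable study subject: 180 days of recording, 75 bpm baseline,
planted daily/weekly/2-weekly/monthly heart-rate cycles (amplitudes 8, 4,
3, 4 bpm), AR(1) noise with marginal SD 3 bpm and lag-1 coefficient 0.95
at the 5-minute step, 18% of samples masked, and self-reported events at
0.22/day locked (von Mises concentration $\kappa = 8$) to the daily and
weekly cycles. Missingness is generated in contiguous blocks (geometric
lengths, mean 6 h) rather than i.i.d., because gap filling is only
stressed by runs. Event times are drawn by thinning a homogeneous rate
with the product of per-cycle von Mises densities, each normalised by
$I_0(\kappa)$ so the expected count stays near rate × duration, and
snapped to the 5-minute grid. Fixed seeds make both generators
bit-identical; planted ground truth travels with the objects as a `truth`
attribute.

What the generator does *not* emulate: heart-rate variability proper,
exercise and artefact transients, chronotype shifts, reporting bias that
varies with time of day, and cycles whose period or amplitude drift.
Passing tests on synthetic data therefore demonstrate that the pipeline
recovers the structure it models — stationary sinusoidal cycles with
phase-locked events — not that real diaries behave this way.

## Numerical choices and edge cases

* Phases are always wrapped to $(-\pi, \pi]$; bin membership is left-open /
  right-closed with a $10^{-9}$ guard so phases computed along different
  arithmetic paths cannot straddle a bin edge by floating-point jitter.
* Filtering is applied to the z-scored gap-filled series with reflection
  padding of one band-high period per end; `signal::filtfilt` keeps the
  phase response zero.
* The wavelet spectrum is computed scale by scale from one FFT of the
  zero-padded series, averaging power over the unpadded support only.
* Sub-6-hour wavelet peaks are not forecastable on the hourly grid and are
  excluded from the forecaster (detection itself still reports them).
* An empty training window, an all-missing heart-rate series, a constant
  likelihood series and a zero-amplitude projection all produce explicit
  errors, warnings or degeneracy flags rather than silent nonsense.
* All timestamps are UTC throughout.

## Problem sizes used by the test-suite

The packaged validation suite runs the whole pipeline at desk scale:
parameter-recovery checks use 120–150-day records (20–50 seeds);
forecast-skill checks use 240-day records with 60-day horizons (20 seeds);
the null-calibration study of the surrogate test uses 200 unlocked
150-day runs. These sizes were chosen so the Monte-Carlo bands quoted in
the tests (e.g. ≥ 90% recovery, 2–9% type-I error) are meaningful while
the suite stays comfortably runnable on a laptop.

## Known limitations

* Cycle models are sinusoidal; strongly non-sinusoidal rhythms are only
  captured through their fundamental.
* The daily-resolution forecast is the plain mean of hourly likelihoods,
  so it is not calibrated as a probability of a seizure *day*; its AUC is
  meaningful, its Brier skill against a daily reference is conservative.
* The surrogate test relocates events uniformly; it does not preserve
  inter-event-interval structure.
* Forecast uncertainty (intervals around the projected likelihood) is not
  modelled.
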