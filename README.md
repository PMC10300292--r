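# cyclecast

Seizure risk forecasting from multiday cycles of wearable heart rate and
self-reported seizure diaries.

Many people with epilepsy have *multidien* rhythms: seizure probability
rises and falls with cycles of about a day, a week, a fortnight or a month,
and the same cycles show up in heart rate recorded by a consumer
smartwatch. `cyclecast` turns those two easily collected streams — a
5-minute heart-rate series and a timestamped event diary — into a rolling,
hourly seizure-likelihood forecast projected up to 60 days ahead, and
scores that forecast the way a prospective trial would.

The pipeline:

* **Cycle detection.** Heart-rate cycles: continuous Morlet wavelet
  transform, with significant peaks of the global (time-averaged) power
  spectrum tested against an AR(1) red-noise background. Diary cycles:
  phase-locking of event times to fixed sinusoids (candidate periods 1–70 d
  in 0.5-d steps, capped at half the record), measured by the
  synchronization index `SI = |mean(exp(i*theta_n))|`, retained at
  `SI >= 0.3`.
* **Phase.** Zero-phase second-order Butterworth bandpass (bandwidth 30% of
  the central frequency) plus Hilbert transform for heart-rate cycles;
  `2*pi*t/P` for diary cycles.
* **Likelihood.** 18 phase bins per cycle; per-bin likelihood = seizure
  hours in the bin / hours the bin presented; cycles and modalities
  combined by the geometric mean of odds
  (`p = prod(p_i/(1-p_i))^(1/n)`, `p_s = p/(1+p)`); two fitted cutoffs
  label each hour low/medium/high risk.
* **Projection.** Additive model `y = g(t) + s(t) + e` (piecewise-linear
  trend + Fourier seasonality) for heart-rate cycles; exact sinusoids for
  diary cycles.
* **Pseudo-prospective evaluation.** Forecasts reissued at midnight after
  every seizure or every 7 days; segments concatenated causally; scored by
  time-in-warning ROC AUC, sensitivity / time-in-high, Brier skill score,
  and a 200-shuffle surrogate significance test, at hourly and daily
  resolution, per modality (diary, heart rate, combined).

A synthetic-data generator (`scenario_config()`, `generate_hr()`,
`generate_events()`) plants known cycles and von Mises phase-locked events
so the whole pipeline is testable without any patient data.

## Worked example

Simulate a participant with daily/weekly/2-weekly/monthly heart-rate
cycles and events locked to the daily and weekly cycles, then forecast
pseudo-prospectively from the 10th seizure onward:

```r
library(cyclecast)

cfg   <- scenario_config(duration = 200, seed = 7)
hr    <- generate_hr(cfg)
diary <- generate_events(cfg, hr)
diary
#> <event_diary> 43 events, 2020-01-01T01:20:00Z .. 2020-07-15T02:00:00Z

cut0 <- initial_cutoff(diary)      # midnight after the 10th seizure
pp <- run_pseudo_prospective(NULL, diary, cut0,
                             hr$start + 200 * 86400, "diary")
pp
#> <pseudo_prospective> diary: 3936 h (164.0 d), 35 issues, 33 events

evaluate_forecast(pp, n_shuffles = 200, seed = 1)
#> <evaluation_report> hourly: AUC 0.938 (above chance), BSS 0.017, p 0.005
#>   sensitivity 17%, time in high 1% over 29 event steps

evaluate_forecast(daily_average(pp), n_shuffles = 200, seed = 1)
#> <evaluation_report> daily: AUC 0.691 (above chance), BSS -0.181, p 0.005
```

Reading the output: over the 164 evaluated days the model was retrained 35
times (after each seizure or weekly); the hourly forecast separates seizure
hours from the rest with a time-in-warning AUC of 0.94, far above its
200-shuffle surrogate null (p = 0.005); at the fitted thresholds it spends
1% of the time in high risk and catches 17% of seizure hours there. Passing
`hr` instead of `NULL` adds the heart-rate and combined modalities, and
`select_best()` picks the modality with the highest AUC.

`run_pipeline(run_config(...))` does all of the above from CSV inputs and
writes forecasts, model JSON and evaluation JSON to disk; a thin CLI over
the same functions lives at `inst/cli/cyclecast.R`
(`simulate` / `run` / `evaluate` subcommands).

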