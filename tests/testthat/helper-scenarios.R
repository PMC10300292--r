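# Shared fixture builders. Everything is generated in code; no data files.

T0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

# A noiseless hr_series holding an arbitrary signal on the 5-min grid.
hr_from_signal <- function(values, start = T0) {
  hr_series(start, values)
}

# Pure sinusoid heart-rate series: baseline + A*cos(2 pi t / P + phi).
sinusoid_hr <- function(days, period, amplitude = 5, baseline = 70,
                        phi = 0, start = T0) {
  t <- (seq_len(days * 288) - 1) / 288
  hr_series(start, baseline + amplitude * cos(2 * pi * t / period + phi))
}

# Diary with events at exact multiples of `period` days from `start`.
periodic_diary <- function(n, period, start = T0, offset_days = 0) {
  event_diary(start + ((seq_len(n) - 1) * period + offset_days) * 86400)
}

# Small scenario used in several end-to-end tests: diary-only forecasting
# with strong locking to daily + weekly cycles.
diary_scenario <- function(seed, duration = 150, kappa = 8,
                           locking = c(1, 7), event_rate = 0.22) {
  scenario_config(duration = duration, kappa = kappa,
                  locking_periods = locking,
                  locking_phases = rep(0, length(locking)),
                  event_rate = event_rate, seed = seed)
}

# Independent brute-force time-in-warning AUC: enumerate every unique
# threshold, count fractions directly.
oracle_auc <- function(likelihood, labels) {
  thr <- sort(unique(likelihood), decreasing = TRUE)
  x <- vapply(thr, function(c) mean(likelihood >= c), numeric(1))
  y <- vapply(thr, function(c) mean(likelihood[labels] >= c), numeric(1))
  x <- c(0, x); y <- c(0, y)
  if (max(x) < 1) { x <- c(x, 1); y <- c(y, 1) }
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
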