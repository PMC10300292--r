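test_that("fill_missing imputes the training mean and keeps the mask", {
  hr <- sinusoid_hr(2, 1, amplitude = 0, baseline = 70)
  expect_identical(fill_missing(hr, 65)$bpm, hr$bpm)   # nothing to fill

  bpm <- hr$bpm; bpm[100:111] <- NA
  gappy <- hr_series(T0, bpm)
  filled <- fill_missing(gappy, 70)
  expect_equal(filled$bpm[100:111], rep(70, 12))
  expect_true(all(filled$missing[100:111]))
  expect_identical(filled$bpm[-(100:111)], hr$bpm[-(100:111)])

  all_na <- hr_series(T0, rep(NA_real_, 288))
  expect_equal(fill_missing(all_na, 65)$bpm, rep(65, 288))
  expect_error(fill_missing(all_na), "entirely missing")
})

test_that("band edges follow the symmetric 30% bandwidth rule", {
  be <- band_edges(8, 0.3)
  expect_equal(be[["band_low"]], 5.6)
  expect_equal(be[["band_high"]], 10.4)
  # band collapses onto the period as the fraction shrinks
  expect_equal(unname(band_edges(8, 1e-9)), c(8, 8), tolerance = 1e-6)
  expect_error(band_edges(-1), "period")
  expect_error(band_edges(8, 1.2), "bandwidth_fraction")
})

test_that("candidate periods run 1..70 in half-day steps, capped at half the span", {
  expect_equal(max(candidate_periods(20)), 10)
  p200 <- candidate_periods(200)
  expect_equal(p200, seq(1, 70, by = 0.5))
  expect_length(p200, 139)
  expect_length(candidate_periods(1.5), 0)
})

test_that("sinusoid phase wraps correctly and hits the quarter-cycle marks", {
  P <- 14
  ref <- T0
  at <- function(days) sinusoid_phase(ref + days * 86400, P, ref)$phase
  expect_equal(at(0), 0)
  expect_equal(at(P), 0)
  expect_equal(at(P / 4), pi / 2)
  expect_equal(at(P / 2), pi)
  expect_equal(at(3 * P / 4), -pi / 2)
  # all phases in (-pi, pi]
  ph <- sinusoid_phase(ref + seq(0, 100, by = 0.13) * 86400, 7.5, ref)$phase
  expect_true(all(ph > -pi & ph <= pi))
})

test_that("compute_si matches direct complex summation", {
  expect_equal(compute_si(rep(1.3, 17)), 1)
  expect_equal(compute_si(c(0, pi / 2, pi, 3 * pi / 2)), 0)
  expect_equal(compute_si(c(0, 0, pi / 2)), sqrt(5) / 3)
  expect_error(compute_si(numeric(0)), "no event phases")
  # rotation invariance and oracle equivalence on random sets
  set.seed(1)
  for (i in 1:25) {
    th <- runif(sample(2:40, 1), -pi, pi)
    oracle <- Mod(sum(exp(1i * th))) / length(th)
    expect_equal(compute_si(th), oracle)
    rot <- runif(1, -pi, pi)
    expect_equal(compute_si(th + rot), compute_si(th), tolerance = 1e-12)
  }
})

test_that("bandpass extraction passes the central period and rejects out-of-band", {
  hr <- sinusoid_hr(60, 7, amplitude = 4, baseline = 70)
  cy <- cycle_spec("hr", 7, band_low = 5.6 * 7 / 8, band_high = 10.4 * 7 / 8)
  y <- extract_cycle(hr, cy)
  mid <- 5000:12000
  # zero-phase contract: peaks of the output align with peaks of the input
  x <- (hr$bpm - mean(hr$bpm)) / sd(hr$bpm)
  expect_gt(cor(y[mid], x[mid]), 0.999)
  expect_gt(sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2)), 0.95)

  # sinusoid at 4x the period is attenuated below 10%
  hr4 <- sinusoid_hr(120, 28, amplitude = 4, baseline = 70)
  y4 <- extract_cycle(hr4, cy)
  x4 <- (hr4$bpm - mean(hr4$bpm)) / sd(hr4$bpm)
  mid4 <- 10000:24000
  expect_lt(sqrt(mean(y4[mid4]^2)) / sqrt(mean(x4[mid4]^2)), 0.1)

  # constant input: ~zero output
  flat <- hr_from_signal(rep(70, 288 * 30))
  expect_lt(max(abs(extract_cycle(flat, cy))), 1e-8)

  # band outside the representable frequencies errors
  tight <- cycle_spec("hr", 5 / 1440 * 1.5, band_low = 5 / 1440 * 1.1,
                      band_high = 5 / 1440 * 2)
  expect_error(extract_cycle(hr, tight), "not representable")
})

test_that("hilbert phase recovers the analytic phase of sinusoids", {
  days <- 28; P <- 7
  hr <- sinusoid_hr(days, P, amplitude = 1, baseline = 0)
  ph <- hilbert_phase(hr$bpm, T0, hourly = FALSE)
  t_days <- (seq_len(days * 288) - 1) / 288
  truth <- wrap_pi(2 * pi * t_days / P)
  interior <- which(t_days > 2 & t_days < days - 2)
  err <- abs(wrap_pi(ph$phase[interior] - truth[interior]))
  expect_lt(max(err), 0.05)
  # cos peaks at phase 0, minima at +-pi
  peaks <- interior[abs(t_days[interior] %% P) < 1e-9]
  expect_lt(max(abs(ph$phase[peaks])), 0.05)
  # sin(2 pi t / P) = cos(... - pi/2): phase -pi/2 at cycle starts
  hs <- sin(2 * pi * t_days / P)
  phs <- hilbert_phase(hs, T0, hourly = FALSE)
  expect_lt(max(abs(phs$phase[peaks] + pi / 2)), 0.05)
  expect_error(hilbert_phase(rep(0, 100), T0), "all-zero")
})

test_that("extract + hilbert recovers the planted phase of noiseless cycles", {
  P <- 7
  hr <- sinusoid_hr(70, P, amplitude = 5, baseline = 70, phi = 0.8)
  cy <- cycle_spec("hr", P, band_low = 0.7 * P, band_high = 1.3 * P)
  ph <- hilbert_phase(extract_cycle(hr, cy), T0)
  t_days <- time_days(ph$times, T0)
  truth <- wrap_pi(2 * pi * t_days / P + 0.8)
  interior <- t_days > 2 * P & t_days < 70 - 2 * P
  expect_lt(max(abs(wrap_pi(ph$phase[interior] - truth[interior]))), 0.05)
  # circular correlation with ground truth
  expect_gt(cor(cos(ph$phase[interior]), cos(truth[interior])), 0.99)
})

test_that("wavelet detection finds a strong planted cycle and nothing in flat series", {
  hr <- sinusoid_hr(90, 7, amplitude = 5, baseline = 70)
  bpm <- hr$bpm + rnorm(length(hr$bpm), sd = 0.5)
  set.seed(5)
  cycles <- detect_hr_cycles(hr_series(T0, bpm))
  expect_gt(length(cycles), 0)
  best <- cycles[[which.min(vapply(cycles, function(c) abs(c$period - 7),
                                   numeric(1)))]]
  expect_lt(abs(best$period - 7), 0.5)
  expect_true(all(vapply(cycles, function(c) c$period <= 45, logical(1))))

  expect_length(detect_hr_cycles(hr_from_signal(rep(70, 288 * 30))), 0)
})

test_that("wavelet false-detection rate on white noise matches the test's confidence", {
  set.seed(7)
  counts95 <- counts99 <- numeric(20)
  for (i in 1:20) {
    hr <- hr_from_signal(70 + rnorm(30 * 288))
    counts95[i] <- length(detect_hr_cycles(hr, significance = 0.95))
    counts99[i] <- length(detect_hr_cycles(hr, significance = 0.999))
  }
  # a 95% pointwise test over ~180 correlated scales admits only a small
  # handful of spurious peaks, and tightening the confidence reduces them
  expect_lt(mean(counts95), 3)
  expect_lt(mean(counts99), mean(counts95))
})

test_that("detect_hr_cycles never returns periods above half the record", {
  for (seed in 1:3) {
    set.seed(seed)
    days <- 40
    hr <- hr_from_signal(70 + 3 * cos(2 * pi * seq_len(days * 288) / 288 / 7) +
                           rnorm(days * 288))
    periods <- vapply(detect_hr_cycles(hr), `[[`, numeric(1), "period")
    expect_true(all(periods <= days / 2))
  }
})

test_that("event-cycle detection keeps truly periodic diaries with SI 1", {
  d <- periodic_diary(12, 7)
  cycles <- detect_event_cycles(d, training_span = 84, reference_time = T0)
  periods <- vapply(cycles, `[[`, numeric(1), "period")
  expect_true(7 %in% periods)
  expect_equal(cycles[[which(periods == 7)[1]]]$si, 1)
  expect_error(detect_event_cycles(event_diary(), 84, reference_time = T0),
               "empty diary")
})

test_that("uniform diaries rarely pass the SI threshold at N = 200", {
  retained <- vapply(1:10, function(seed) {
    set.seed(seed)
    d <- event_diary(T0 + sort(runif(200, 0, 400)) * 86400)
    length(detect_event_cycles(d, training_span = 400, reference_time = T0))
  }, numeric(1))
  # E[SI] ~ 0.06 at N=200; threshold 0.3 is far in the tail
  expect_equal(mean(retained > 0), 0)
})

test_that("planted 14-day locking is retained with kappa = 8 at N ~ 30", {
  hits <- vapply(1:50, function(seed) {
    cfg <- scenario_config(duration = 140, kappa = 8, locking_periods = 14,
                           locking_phases = 0, event_rate = 30 / 140,
                           missing_fraction = 0, seed = seed)
    hr <- generate_hr(cfg)
    d <- generate_events(cfg, hr)
    if (length(d$times) == 0) return(FALSE)
    cycles <- detect_event_cycles(d, 140, reference_time = hr$start)
    periods <- vapply(cycles, `[[`, numeric(1), "period")
    any(abs(periods - 14) <= 0.5)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
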