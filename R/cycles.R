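#' Fill heart-rate gaps with the training mean
#'
#' Missing segments are set to a constant value, the mean heart rate of the
#' training data. The missing mask is retained so downstream code can still
#' distinguish observed from imputed samples.
#'
#' @param hr an [hr_series()].
#' @param training_mean BPM value used for imputation; defaults to the mean
#'   of the observed samples of `hr` itself.
#' @return an [hr_series()] with no `NA` values and the original mask.
#' @export
fill_missing <- function(hr, training_mean = NULL) {
  if (is.null(training_mean)) {
    if (all(hr$missing)) {
      stopf("fill_missing: series is entirely missing and no training mean supplied")
    }
    training_mean <- mean(hr$bpm[!hr$missing])
  }
  if (!is.finite(training_mean)) stopf("fill_missing: training_mean must be finite")
  bpm <- hr$bpm
  bpm[hr$missing] <- training_mean
  hr_series(hr$start, bpm, hr$missing)
}

#' Bandpass edges for cycle extraction
#'
#' The filter bandwidth is a fraction of the central frequency; in the period
#' domain the edges are symmetric: `period * (1 -/+ bandwidth_fraction)`.
#' With the default 30% rule an 8-day cycle gets a 5.6-10.4 day passband.
#'
#' @param period central cycle period, days.
#' @param bandwidth_fraction fractional bandwidth in (0, 1); default 0.3.
#' @return named numeric vector `c(band_low, band_high)` in days.
#' @export
#' @examples
#' band_edges(8)  # 5.6, 10.4
band_edges <- function(period, bandwidth_fraction = 0.3) {
  if (!is.finite(period) || period <= 0) stopf("band_edges: period must be > 0")
  if (bandwidth_fraction <= 0 || bandwidth_fraction >= 1) {
    stopf("band_edges: bandwidth_fraction must be in (0, 1)")
  }
  c(band_low = period * (1 - bandwidth_fraction),
    band_high = period * (1 + bandwidth_fraction))
}

#' Candidate seizure-cycle periods
#'
#' Fixed sinusoid periods from 1 day upward in 0.5-day steps, capped at 70
#' days and at half the training-record duration (so longer cycles become
#' admissible as the record grows).
#'
#' @param training_span length of the training record, days.
#' @param max_period overall cap, days (default 70).
#' @param step increment, days (default 0.5).
#' @return numeric vector of periods in days (possibly empty).
#' @export
#' @examples
#' range(candidate_periods(200))  # 1 .. 70
#' max(candidate_periods(20))     # 10
candidate_periods <- function(training_span, max_period = 70, step = 0.5) {
  if (!is.finite(training_span) || training_span <= 0) {
    stopf("candidate_periods: training_span must be > 0")
  }
  cap <- min(max_period, training_span / 2)
  if (cap < 1) return(numeric(0))
  seq(1, cap, by = step)
}

#' Phase of a fixed sinusoid
#'
#' `phase(t) = wrap(2 * pi * (t - reference_time) / period)` into (-pi, pi].
#' The reference is the first timestamp of the training record, so phase 0
#' recurs every `period` days from the record start.
#'
#' @param times POSIXct vector (typically an hourly grid or event times).
#' @param period cycle period, days.
#' @param reference_time POSIXct phase origin.
#' @return a [phase_series()].
#' @export
sinusoid_phase <- function(times, period, reference_time) {
  if (!is.finite(period) || period <= 0) stopf("sinusoid_phase: period must be > 0")
  phase_series(times, wrap_pi(2 * pi * time_days(times, reference_time) / period))
}

#' Synchronization index (phase-locking value)
#'
#' Modulus of the mean unit phasor of the event phases,
#' `SI = | mean(exp(i * theta_n)) |`, where `theta_n` is the phase of the
#' n-th seizure with respect to an underlying cycle. SI = 1 for perfect
#' phase locking, ~0 for uniform phases.
#'
#' @param event_phases numeric vector of phases in radians (N >= 1).
#' @return SI in `[0, 1]`.
#' @export
#' @examples
#' compute_si(c(0, 0, pi / 2))  # sqrt(5)/3
compute_si <- function(event_phases) {
  if (length(event_phases) == 0) stopf("compute_si: no event phases supplied")
  if (any(!is.finite(event_phases))) stopf("compute_si: non-finite phases")
  Mod(mean(exp(1i * event_phases)))
}

# ---------------------------------------------------------------------------
# Morlet continuous wavelet transform and the time-averaged red-noise
# significance test used to find heart-rate cycle periods.
# ---------------------------------------------------------------------------

MORLET_OMEGA0 <- 6           # nondimensional mother-wavelet frequency
MORLET_GAMMA <- 2.32         # decorrelation factor for time-averaged dof
MORLET_FOURIER_FACTOR <- 4 * pi / (MORLET_OMEGA0 + sqrt(2 + MORLET_OMEGA0^2))

# Global (time-averaged) Morlet wavelet power spectrum of a demeaned series.
# dt in days; scales span `min_period` (days) up to max_period with `voices`
# scales per octave. Power is averaged over the unpadded support only.
morlet_global_spectrum <- function(x, dt, min_period = 2 / 24,
                                   max_period = NULL, voices = 24) {
  n <- length(x)
  x <- x - mean(x)
  sigma2 <- stats::var(x)
  if (is.null(max_period)) max_period <- n * dt / 2
  if (max_period < min_period || sigma2 == 0) {
    return(list(periods = numeric(0), power = numeric(0),
                sigma2 = sigma2, n = n, dt = dt, scales = numeric(0)))
  }
  npad <- 2^ceiling(log2(n))
  fx <- stats::fft(c(x, rep(0, npad - n)))
  s0 <- min_period / MORLET_FOURIER_FACTOR
  jmax <- floor(log2(max_period / min_period) * voices)
  scales <- s0 * 2^((0:jmax) / voices)
  omega <- 2 * pi * c(0:(npad / 2), -((npad / 2 - 1):1)) / (npad * dt)
  pos <- omega > 0
  power <- vapply(scales, function(s) {
    psi <- numeric(npad)
    psi[pos] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-(s * omega[pos] - MORLET_OMEGA0)^2 / 2)
    w <- stats::fft(fx * psi, inverse = TRUE) / npad
    mean(Mod(w[seq_len(n)])^2)
  }, numeric(1))
  list(periods = scales * MORLET_FOURIER_FACTOR, power = power,
       sigma2 = sigma2, n = n, dt = dt, scales = scales)
}

# Time-averaged significance level for the global wavelet spectrum against a
# theoretical AR(1) red-noise background with lag-1 autocorrelation `alpha`
# (Torrence & Compo style chi-squared test).
morlet_significance <- function(spec, alpha, confidence = 0.95) {
  if (length(spec$periods) == 0) return(numeric(0))
  freq <- spec$dt / spec$periods                    # cycles per sample
  background <- (1 - alpha^2) / (1 + alpha^2 - 2 * alpha * cos(2 * pi * freq))
  dof <- 2 * sqrt(1 + (spec$n * spec$dt / (MORLET_GAMMA * spec$scales))^2)
  spec$sigma2 * background * stats::qchisq(confidence, dof) / dof
}

#' Detect significant heart-rate cycles
#'
#' Applies a continuous Morlet wavelet transform (omega0 = 6, 24 voices per
#' octave, scales from 2 hours up to half the record length) to the
#' gap-filled heart-rate signal and returns the local maxima of the global
#' (time-averaged) wavelet power spectrum that exceed a time-averaged
#' red-noise significance level. The AR(1) background is estimated from the
#' lag-1 autocorrelation of the gap-filled series. Near-duplicate peaks
#' within one scale step are merged, keeping the higher power.
#'
#' @param hr a gap-filled [hr_series()] (see [fill_missing()]).
#' @param significance confidence level of the red-noise test (default 0.95).
#' @param bandwidth_fraction fractional filter bandwidth stored on each
#'   returned cycle (default 0.3).
#' @param min_period shortest period searched, days (default 2 hours).
#' @return list of [cycle_spec()] objects (source `"hr"`), sorted by
#'   descending power; empty when the record is too short or flat.
#' @export
detect_hr_cycles <- function(hr, significance = 0.95, bandwidth_fraction = 0.3,
                             min_period = 2 / 24) {
  if (anyNA(hr$bpm)) stopf("detect_hr_cycles: gap-fill the series first (fill_missing)")
  dt <- hr$step_secs / SECS_PER_DAY
  spec <- morlet_global_spectrum(hr$bpm, dt, min_period = min_period)
  if (length(spec$periods) < 3 || spec$sigma2 == 0) return(list())
  x <- hr$bpm - mean(hr$bpm)
  alpha <- max(0, stats::cor(x[-1], x[-length(x)]))
  level <- morlet_significance(spec, alpha, significance)
  g <- spec$power
  is_peak <- c(FALSE, diff(sign(diff(g))) < 0, FALSE)
  keep <- which(is_peak & g > level)
  if (length(keep) == 0) return(list())
  # merge peaks within one scale step (adjacent indices)
  groups <- cumsum(c(1, diff(keep) > 1))
  keep <- vapply(split(keep, groups), function(idx) idx[which.max(g[idx])],
                 integer(1))
  ord <- keep[order(g[keep], decreasing = TRUE)]
  lapply(ord, function(i) {
    be <- band_edges(spec$periods[i], bandwidth_fraction)
    cycle_spec("hr", spec$periods[i], band_low = be[[1]], band_high = be[[2]],
               power = g[i])
  })
}

#' Extract one heart-rate cycle by zero-phase bandpass filtering
#'
#' Applies a zero-phase (forward-backward), second-order Butterworth
#' bandpass between the cycle's band edges to the z-scored, gap-filled
#' series. Edge effects are reduced by reflection padding of one band-high
#' period at each end before filtering.
#'
#' @param hr a gap-filled [hr_series()].
#' @param cycle a [cycle_spec()] with band edges (or any object with
#'   `band_low`/`band_high` in days).
#' @return numeric vector on the same 5-minute grid as `hr` (z-score units).
#' @export
extract_cycle <- function(hr, cycle) {
  if (anyNA(hr$bpm)) stopf("extract_cycle: gap-fill the series first")
  dt <- hr$step_secs / SECS_PER_DAY
  f_nyquist <- 0.5 / dt                       # cycles per day
  f_lo <- 1 / cycle$band_high
  f_hi <- 1 / cycle$band_low
  if (f_hi >= f_nyquist) {
    stopf("extract_cycle: band [%.3g, %.3g] days not representable at the 5-min grid",
          cycle$band_low, cycle$band_high)
  }
  x <- hr$bpm
  s <- stats::sd(x)
  x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  pad <- min(length(x) - 1, ceiling(cycle$band_high / dt))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[length(x) - seq_len(pad) + 1]))
  bf <- signal::butter(2, c(f_lo, f_hi) / f_nyquist, type = "pass")
  y <- signal::filtfilt(bf, xp)
  y[pad + seq_along(x)]
}

# FFT-based analytic signal (Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic-signal angle of a band-limited signal (typically
#' the output of [extract_cycle()]) on the native 5-minute grid, then
#' subsamples it to the hourly forecast grid.
#'
#' @param x numeric band-limited signal on the 5-minute grid.
#' @param start POSIXct timestamp of `x[1]`.
#' @param step_secs sample step of `x` in seconds (default 300).
#' @param hourly return the phase on the hourly grid (default) or on the
#'   native grid.
#' @return a [phase_series()].
#' @export
hilbert_phase <- function(x, start, step_secs = HR_STEP_SECS, hourly = TRUE) {
  if (all(x == 0)) stopf("hilbert_phase: all-zero signal has undefined phase")
  ph <- wrap_pi(Arg(analytic_signal(x)))
  if (hourly && step_secs != 3600) {
    stride <- 3600 / step_secs
    if (stride != round(stride)) stopf("hilbert_phase: step does not divide one hour")
    idx <- seq(1, length(x), by = stride)
    phase_series(start + 3600 * (seq_along(idx) - 1), ph[idx])
  } else {
    phase_series(start + step_secs * (seq_along(x) - 1), ph)
  }
}

#' Detect significant seizure cycles from an event diary
#'
#' For every candidate period (1-70 days in 0.5-day steps, capped at half
#' the training span) the phases of the training events under a fixed
#' sinusoid are computed and their synchronization index taken; periods
#' with SI at or above the threshold (default 0.3, 'moderate' phase
#' clustering) are returned, sorted by descending SI. Runs of adjacent
#' qualifying periods are merged, keeping the peak SI.
#'
#' @param diary an [event_diary()] restricted to the training window.
#' @param training_span training-record length, days.
#' @param si_threshold minimum SI (default 0.3).
#' @param reference_time phase origin (first timestamp of the training
#'   record).
#' @return list of [cycle_spec()] objects (source `"diary"`).
#' @export
detect_event_cycles <- function(diary, training_span, si_threshold = 0.3,
                                reference_time) {
  if (length(diary$times) == 0) stopf("detect_event_cycles: empty diary")
  periods <- candidate_periods(training_span)
  if (length(periods) == 0) return(list())
  t_ev <- time_days(diary$times, reference_time)
  si <- vapply(periods, function(p) compute_si(wrap_pi(2 * pi * t_ev / p)),
               numeric(1))
  qualify <- si >= si_threshold
  if (!any(qualify)) return(list())
  # keep the local maxima of the SI curve among qualifying periods: runs of
  # adjacent qualifying candidates can span harmonically related cycles, so
  # only true near-duplicate neighbours are merged
  n <- length(si)
  local_max <- si >= c(-Inf, si[-n]) & si > c(si[-1], -Inf)
  keep <- which(qualify & local_max)
  if (length(keep) == 0) keep <- which.max(si)
  ord <- keep[order(si[keep], decreasing = TRUE)]
  lapply(ord, function(i) cycle_spec("diary", periods[i], si = si[i]))
}
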