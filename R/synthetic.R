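#' Scenario configuration for the synthetic-data generator
#'
#' Defines a simulated participant: a baseline heart rate modulated by a sum
#' of sinusoidal cycles plus AR(1) noise and blocky missingness, together
#' with a seizure diary whose events are phase-locked (von Mises) to chosen
#' cycles. Defaults emulate a typical study participant: daily, weekly,
#' 2-weekly and monthly heart-rate cycles, ~18% device non-wear, and a
#' reporting rate of ~0.22 events/day with strong locking to the daily and
#' weekly cycles.
#'
#' @param duration recording length in days.
#' @param hr_baseline mean heart rate in BPM.
#' @param cycle_periods periods of planted heart-rate cycles, days
#'   (strictly positive, distinct).
#' @param cycle_amplitudes amplitude of each cycle, BPM (same length as
#'   `cycle_periods`).
#' @param cycle_phases phase offset of each cycle at the record start,
#'   radians.
#' @param noise_sd marginal standard deviation of the AR(1) noise, BPM.
#' @param ar1_coeff AR(1) coefficient at the 5-minute step, in `[0, 1)`.
#' @param missing_fraction target fraction of masked samples, in `[0, 1)`.
#' @param event_rate mean seizure reporting rate, events/day (> 0 unless the
#'   diary is meant to be empty).
#' @param locking_periods cycle periods (days) the events phase-lock to;
#'   usually a subset of `cycle_periods`, but any pure sinusoid reference is
#'   allowed.
#' @param locking_phases preferred phase of each locking cycle, radians
#'   (recycled; default 0 = events cluster at the cosine peak).
#' @param kappa von Mises concentration of the locking (>= 0; 0 = no
#'   locking, uniform phases).
#' @param seed integer seed making both generators reproducible.
#' @return a validated list of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config(duration = 30, seed = 1)
#' hr <- generate_hr(cfg)
#' diary <- generate_events(cfg, hr)
scenario_config <- function(duration = 180,
                            hr_baseline = 75,
                            cycle_periods = c(1, 7, 14, 28),
                            cycle_amplitudes = c(8, 4, 3, 4),
                            cycle_phases = rep(0, length(cycle_periods)),
                            noise_sd = 3,
                            ar1_coeff = 0.95,
                            missing_fraction = 0.18,
                            event_rate = 0.22,
                            locking_periods = c(1, 7),
                            locking_phases = rep(0, length(locking_periods)),
                            kappa = 8,
                            seed = 1L) {
  cfg <- list(duration = duration, hr_baseline = hr_baseline,
              cycle_periods = cycle_periods,
              cycle_amplitudes = cycle_amplitudes,
              cycle_phases = cycle_phases, noise_sd = noise_sd,
              ar1_coeff = ar1_coeff, missing_fraction = missing_fraction,
              event_rate = event_rate, locking_periods = locking_periods,
              locking_phases = rep_len(locking_phases,
                                       length(locking_periods)),
              kappa = kappa, seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stopf("scenario_config: field '%s' %s", field, msg)
  }
  chk(is.numeric(cfg$duration) && cfg$duration > 0, "duration", "must be > 0")
  chk(is.finite(cfg$hr_baseline), "hr_baseline", "must be finite")
  chk(all(cfg$cycle_periods > 0), "cycle_periods", "must be strictly positive")
  chk(!anyDuplicated(cfg$cycle_periods), "cycle_periods", "must be distinct")
  chk(length(cfg$cycle_amplitudes) == length(cfg$cycle_periods),
      "cycle_amplitudes", "must match cycle_periods in length")
  chk(all(cfg$cycle_amplitudes >= 0), "cycle_amplitudes", "must be >= 0")
  chk(length(cfg$cycle_phases) == length(cfg$cycle_periods),
      "cycle_phases", "must match cycle_periods in length")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$ar1_coeff >= 0 && cfg$ar1_coeff < 1, "ar1_coeff", "must be in [0, 1)")
  chk(cfg$missing_fraction >= 0 && cfg$missing_fraction < 1,
      "missing_fraction", "must be in [0, 1)")
  chk(cfg$event_rate >= 0, "event_rate", "must be >= 0")
  chk(all(cfg$locking_periods > 0), "locking_periods", "must be > 0")
  chk(cfg$kappa >= 0, "kappa", "must be >= 0")
  invisible(cfg)
}

SYNTH_ORIGIN <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

# Mean block length of simulated device non-wear (hours). Gap filling is only
# stressed by runs, so missingness comes in contiguous geometric blocks.
MISSING_BLOCK_HOURS <- 6

#' Generate a synthetic heart-rate series
#'
#' 5-minute grid of `duration * 288` samples:
#' baseline + sum of planted cosines + AR(1) noise (innovations scaled so the
#' marginal SD equals `noise_sd`), with `missing_fraction` of samples masked
#' in contiguous blocks (geometric lengths, mean 6 h) to mimic non-wear.
#'
#' @param config a [scenario_config()].
#' @return an [hr_series()]; planted ground truth is attached as
#'   `attr(, "truth")`.
#' @export
generate_hr <- function(config) {
  validate_scenario_config(config)
  n <- round(config$duration * SECS_PER_DAY / HR_STEP_SECS)
  t_days <- (seq_len(n) - 1) * HR_STEP_SECS / SECS_PER_DAY
  signal <- rep(config$hr_baseline, n)
  for (k in seq_along(config$cycle_periods)) {
    signal <- signal + config$cycle_amplitudes[k] *
      cos(2 * pi * t_days / config$cycle_periods[k] + config$cycle_phases[k])
  }
  with_seed(config$seed, {
    if (config$noise_sd > 0) {
      innov_sd <- config$noise_sd * sqrt(1 - config$ar1_coeff^2)
      noise <- as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd),
                                        config$ar1_coeff,
                                        method = "recursive"))
      signal <- signal + noise
    }
    missing <- rep(FALSE, n)
    if (config$missing_fraction > 0) {
      target <- round(config$missing_fraction * n)
      block_mean <- MISSING_BLOCK_HOURS * 3600 / HR_STEP_SECS
      guard <- 0L
      while (sum(missing) < target && guard < 100000L) {
        len <- 1L + stats::rgeom(1, 1 / block_mean)
        start <- sample.int(n, 1)
        idx <- start:min(n, start + len - 1L)
        fresh <- idx[!missing[idx]]
        excess <- sum(missing) + length(fresh) - target
        if (excess > 0) fresh <- fresh[seq_len(length(fresh) - excess)]
        missing[fresh] <- TRUE
        guard <- guard + 1L
      }
    }
  })
  bpm <- signal
  bpm[missing] <- NA_real_
  out <- hr_series(SYNTH_ORIGIN, bpm, missing)
  attr(out, "truth") <- list(periods = config$cycle_periods,
                             amplitudes = config$cycle_amplitudes,
                             phases = config$cycle_phases,
                             clean = signal,
                             seed = config$seed)
  out
}

#' Generate a phase-locked synthetic event diary
#'
#' Events are drawn by thinning a homogeneous rate on the 5-minute grid: the
#' acceptance weight at time t is the product over locking cycles of the von
#' Mises density (concentration `kappa`) of the cycle phase, normalised so
#' the expected count stays near `event_rate * duration`. Event times are
#' snapped to the grid.
#'
#' @param config a [scenario_config()].
#' @param hr the matching [generate_hr()] output (fixes the time span).
#' @return an [event_diary()]; planted ground truth (locking periods,
#'   preferred phases, kappa, seed) is attached as `attr(, "truth")`.
#' @export
generate_events <- function(config, hr) {
  validate_scenario_config(config)
  if (config$kappa < 0) stopf("scenario_config: field 'kappa' must be >= 0")
  n <- length(hr$bpm)
  t_days <- (seq_len(n) - 1) * HR_STEP_SECS / SECS_PER_DAY
  # match the planted HR cycle phase offset where a locking period is planted
  phase_off <- vapply(config$locking_periods, function(p) {
    i <- match(p, config$cycle_periods)
    if (is.na(i)) 0 else config$cycle_phases[i]
  }, numeric(1))
  w <- rep(1, n)
  if (config$kappa > 0 && length(config$locking_periods) > 0) {
    for (k in seq_along(config$locking_periods)) {
      th <- 2 * pi * t_days / config$locking_periods[k] + phase_off[k]
      w <- w * exp(config$kappa * cos(th - config$locking_phases[k])) /
        besselI(config$kappa, 0)
    }
  }
  p <- pmin(1, config$event_rate * (HR_STEP_SECS / SECS_PER_DAY) * w)
  times <- with_seed(config$seed + 1L, {
    hit <- stats::runif(n) < p
    hr_times(hr)[hit]
  })
  out <- event_diary(times)
  attr(out, "truth") <- list(locking_periods = config$locking_periods,
                             locking_phases = config$locking_phases,
                             phase_offsets = phase_off,
                             kappa = config$kappa,
                             event_rate = config$event_rate,
                             seed = config$seed)
  out
}

#' Write a synthetic scenario to disk
#'
#' Emits `hr.csv` (`timestamp,bpm`; empty field for missing samples),
#' `diary.csv` (`timestamp`) and `truth.json` (planted periods, phases,
#' kappa, seed) into `dir`.
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hr <- generate_hr(config)
  diary <- generate_events(config, hr)
  paths <- c(hr = file.path(dir, "hr.csv"),
             diary = file.path(dir, "diary.csv"),
             truth = file.path(dir, "truth.json"))
  write_hr_csv(hr, paths[["hr"]])
  write_diary_csv(diary, paths[["diary"]])
  truth <- list(
    hr_cycles = list(periods = config$cycle_periods,
                     amplitudes = config$cycle_amplitudes,
                     phases = config$cycle_phases),
    locking = attr(diary, "truth")[c("locking_periods", "locking_phases",
                                     "kappa", "event_rate")],
    seed = config$seed
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
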