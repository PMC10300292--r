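# Training, forecast issuance, pseudo-prospective walk-forward and daily
# aggregation.

#' Forecasting constants
#'
#' All tunables of the forecasting pipeline with their standard defaults:
#' SI threshold 0.3, 18 phase bins, 60-day horizon, weekly reissue, 10
#' training seizures, 200 surrogate shuffles, 95% wavelet significance.
#'
#' @param si_threshold minimum synchronization index for a cycle to enter
#'   the forecast.
#' @param n_bins phase bins per cycle.
#' @param horizon_days forecast projection horizon.
#' @param reissue_interval_days maximum time between forecast reissues.
#' @param n_training_events events required before the first forecast.
#' @param surrogates shuffles for the surrogate significance test.
#' @param significance confidence level of the wavelet red-noise test.
#' @return a list of class `forecast_config`.
#' @export
forecast_config <- function(si_threshold = 0.3, n_bins = 18, horizon_days = 60,
                            reissue_interval_days = 7, n_training_events = 10,
                            surrogates = 200, significance = 0.95) {
  if (si_threshold < 0 || si_threshold > 1) {
    stopf("forecast_config: si_threshold must be in [0, 1]")
  }
  if (significance <= 0 || significance >= 1) {
    stopf("forecast_config: significance must be in (0, 1)")
  }
  if (n_bins < 1 || horizon_days <= 0 || reissue_interval_days <= 0 ||
      n_training_events < 1 || surrogates < 1) {
    stopf("forecast_config: counts and durations must be positive")
  }
  structure(list(si_threshold = si_threshold, n_bins = as.integer(n_bins),
                 horizon_days = horizon_days,
                 reissue_interval_days = reissue_interval_days,
                 n_training_events = as.integer(n_training_events),
                 surrogates = as.integer(surrogates),
                 significance = significance),
            class = "forecast_config")
}

# Shortest usable cycle period (days): projected phases live on the hourly
# grid, so sub-6-hour cycles cannot be bandpassed/phased there.
MIN_FORECAST_PERIOD <- 6 / 24

# Logical mask of hours (on `grid`) containing at least one event.
event_hour_mask <- function(grid, events) {
  as.numeric(grid) %in% as.numeric(unique(trunc(events$times, units = "hours")))
}

# Combine per-cycle bin likelihoods at given phase series into one hourly
# likelihood vector.
cycles_to_likelihood <- function(phases, binliks, n_bins) {
  p_rows <- lapply(seq_along(phases), function(i) {
    binliks[[i]]$p[phase_bin(phases[[i]]$phase, n_bins)]
  })
  combine_likelihoods(p_rows)
}

#' Train a cycle-based seizure forecaster
#'
#' Detects significant cycles on data up to `cutoff` and fits the phase-bin
#' likelihood models and risk thresholds for each modality:
#' \itemize{
#' \item diary: fixed-sinusoid cycles with event-phase SI at or above the
#'   threshold;
#' \item hr: wavelet-significant heart-rate cycles that are also
#'   phase-locked to the events (SI at or above the threshold), plus an
#'   additive model for projecting them;
#' \item combined: the logit combination of the two modality likelihoods.
#' }
#' The initial training cut-off is conventionally midnight of the day the
#' 10th seizure was reported (see [initial_cutoff()]).
#'
#' @param hr an [hr_series()] (or `NULL` for a diary-only forecaster).
#' @param diary an [event_diary()].
#' @param cutoff POSIXct training cut-off; only data strictly before it are
#'   used.
#' @param config a [forecast_config()].
#' @param min_events minimum training events required (defaults to the
#'   configured 10; retraining calls inherit the same floor).
#' @return an object of class `cycle_forecaster`.
#' @export
train_forecaster <- function(hr, diary, cutoff,
                             config = forecast_config(),
                             min_events = config$n_training_events) {
  diary_train <- diary_window(diary, cutoff)
  if (length(diary_train$times) < min_events) {
    stopf(paste0("train_forecaster: only %d events before %s; ",
                 "need %d - choose a later cutoff"),
          length(diary_train$times), format_iso(cutoff), min_events)
  }
  origin <- if (!is.null(hr)) hr$start else
    as.POSIXct(trunc(min(diary$times), units = "days"), tz = "UTC")
  span <- time_days(cutoff, origin)
  grid <- hourly_grid(origin, cutoff)
  ev_mask <- event_hour_mask(grid, diary_train)
  flat_rate <- max(sum(ev_mask) / length(grid), ODDS_EPS)

  modality_model <- function(cycles, phases) {
    if (length(cycles) == 0) {
      series <- rep(flat_rate, length(grid))
      ths <- suppressWarnings(fit_thresholds(series, ev_mask))
      return(list(cycles = list(), binlik = list(), series = series,
                  thresholds = ths, flat = TRUE, rate = flat_rate))
    }
    binlik <- lapply(phases, estimate_bin_likelihoods, events = diary_train,
                     n_bins = config$n_bins)
    series <- cycles_to_likelihood(phases, binlik, config$n_bins)
    list(cycles = cycles, binlik = binlik, series = series,
         thresholds = fit_thresholds(series, ev_mask), flat = FALSE,
         rate = flat_rate)
  }

  # diary modality
  d_cycles <- detect_event_cycles(diary_train, span, config$si_threshold,
                                  reference_time = origin)
  d_phases <- lapply(d_cycles, function(cy)
    sinusoid_phase(grid, cy$period, origin))
  diary_model <- modality_model(d_cycles, d_phases)

  # heart-rate modality
  hr_model <- NULL
  if (!is.null(hr) && hr$start < cutoff) {
    hr_train <- hr_window(hr, cutoff)
    if (!all(hr_train$missing)) {
      training_mean <- mean(hr_train$bpm[!hr_train$missing])
      filled <- fill_missing(hr_train, training_mean)
      detected <- detect_hr_cycles(filled, config$significance)
      detected <- Filter(function(cy) cy$period >= MIN_FORECAST_PERIOD, detected)
      h_phases <- list(); kept <- list()
      for (cy in detected) {
        ph <- hilbert_phase(extract_cycle(filled, cy), filled$start)
        ev_idx <- match(as.numeric(unique(trunc(diary_train$times, units = "hours"))),
                        as.numeric(ph$times))
        ev_idx <- ev_idx[!is.na(ev_idx)]
        if (length(ev_idx) == 0) next
        si <- compute_si(ph$phase[ev_idx])
        if (si >= config$si_threshold) {
          cy$si <- si
          kept <- c(kept, list(cy))
          h_phases <- c(h_phases, list(ph))
        }
      }
      additive <- fit_additive(filled,
                               periods = vapply(detected, `[[`, numeric(1), "period"))
      hr_model <- modality_model(kept, h_phases)
      hr_model$additive <- additive
      hr_model$training_mean <- training_mean
    }
  }

  combined <- NULL
  if (!is.null(hr_model)) {
    c_series <- combine_likelihoods(list(hr_model$series, diary_model$series))
    combined <- list(series = c_series,
                     thresholds = fit_thresholds(c_series, ev_mask))
  }

  structure(list(origin = origin, cutoff = cutoff, config = config,
                 n_train_events = length(diary_train$times),
                 train_grid_hours = length(grid),
                 diary = diary_model, hr = hr_model, combined = combined),
            class = "cycle_forecaster")
}

#' @export
print.cycle_forecaster <- function(x, ...) {
  cat(sprintf("<cycle_forecaster> trained to %s (%d events)\n",
              format_iso(x$cutoff), x$n_train_events))
  per <- function(m) if (is.null(m)) "-" else
    paste(signif(vapply(m$cycles, `[[`, numeric(1), "period"), 3), collapse = ", ")
  cat(sprintf("  diary cycles: %s\n  hr cycles:    %s\n",
              per(x$diary), per(x$hr)))
  invisible(x)
}

#' Initial training cut-off
#'
#' Midnight (UTC) ending the day on which the `n`-th seizure was reported.
#'
#' @param diary an [event_diary()].
#' @param n_training_events number of training seizures (default 10).
#' @return POSIXct cut-off.
#' @export
initial_cutoff <- function(diary, n_training_events = 10) {
  if (length(diary$times) < n_training_events) {
    stopf("initial_cutoff: diary has %d events; need %d",
          length(diary$times), n_training_events)
  }
  midnight_after(diary$times[n_training_events])
}

#' Issue a forecast segment
#'
#' Projects every cycle of the requested modality over the future hourly
#' grid, converts projected phases to per-cycle bin likelihoods, combines
#' them with the logit rule and labels each hour's risk with the fitted
#' thresholds. A modality with no significant cycles yields a flat segment
#' at the training event rate, flagged `flat`.
#'
#' @param model a [train_forecaster()] result.
#' @param issue_time POSIXct issue time (at or after the training cut-off;
#'   default the cut-off itself).
#' @param horizon_days horizon (default from the model's config).
#' @param modality `"diary"`, `"hr"` or `"combined"`.
#' @return object of class `forecast_segment` with hourly `times`,
#'   `likelihood` and `risk`.
#' @export
issue_forecast <- function(model, issue_time = model$cutoff,
                           horizon_days = model$config$horizon_days,
                           modality = c("diary", "hr", "combined")) {
  modality <- match.arg(modality)
  if (issue_time < model$cutoff) {
    stopf("issue_forecast: issue time precedes the training cutoff")
  }
  n_fut <- round(horizon_days * 24)
  if (n_fut == 0) {
    return(structure(list(issue_time = issue_time, horizon_days = 0,
                          modality = modality, times = issue_time[0],
                          likelihood = numeric(0),
                          risk = factor(character(),
                                        levels = c("low", "medium", "high")),
                          flat = FALSE),
                     class = "forecast_segment"))
  }
  times <- issue_time + 3600 * (seq_len(n_fut) - 1)

  diary_lik <- function() {
    m <- model$diary
    if (m$flat || n_fut == 0) return(rep(m$rate, n_fut))
    phases <- lapply(m$cycles, project_event_cycle,
                     reference_time = model$origin, issue_time = issue_time,
                     horizon_days = horizon_days)
    cycles_to_likelihood(phases, m$binlik, model$config$n_bins)
  }
  hr_lik <- function() {
    m <- model$hr
    if (is.null(m)) stopf("issue_forecast: no heart-rate model was trained")
    if (m$flat || n_fut == 0) return(rep(m$rate, n_fut))
    gap_h <- round(as.numeric(difftime(issue_time, model$cutoff, units = "hours")))
    phases <- lapply(m$cycles, function(cy) {
      pr <- project_hr_cycle(m$additive, cy,
                             horizon_days = (gap_h + n_fut) / 24)
      phase_series(times, pr$phase$phase[gap_h + seq_len(n_fut)])
    })
    cycles_to_likelihood(phases, m$binlik, model$config$n_bins)
  }

  lik <- switch(modality,
                diary = diary_lik(),
                hr = hr_lik(),
                combined = {
                  if (is.null(model$combined)) {
                    stopf("issue_forecast: no combined model (heart rate missing)")
                  }
                  combine_likelihoods(list(hr_lik(), diary_lik()))
                })
  ths <- switch(modality, diary = model$diary$thresholds,
                hr = model$hr$thresholds,
                combined = model$combined$thresholds)
  flat <- switch(modality, diary = model$diary$flat, hr = model$hr$flat,
                 combined = model$hr$flat && model$diary$flat)
  structure(list(issue_time = issue_time, horizon_days = horizon_days,
                 modality = modality, times = times, likelihood = lik,
                 risk = classify_risk(lik, ths), flat = flat),
            class = "forecast_segment")
}

#' @export
print.forecast_segment <- function(x, ...) {
  cat(sprintf("<forecast_segment> %s, issued %s, %d h horizon%s\n",
              x$modality, format_iso(x$issue_time), length(x$times),
              if (x$flat) " [flat]" else ""))
  invisible(x)
}

#' Walk-forward pseudo-prospective forecasting
#'
#' Starting at the initial cut-off, trains a forecaster, issues a 60-day
#' segment, and reissues at midnight after every reported seizure or after
#' 7 days since the last issue, whichever comes first. Each evaluation hour
#' takes the likelihood from the most recent segment issued at or before
#' it, so the concatenated series never uses future information; the
#' issuing segment of every hour is recorded in `provenance`.
#'
#' @param hr an [hr_series()] or `NULL` (diary-only).
#' @param diary an [event_diary()].
#' @param initial_cutoff POSIXct start of the evaluation span (midnight
#'   after the 10th training seizure; see [initial_cutoff()]).
#' @param end_time POSIXct end of the evaluation span (exclusive).
#' @param modality `"diary"`, `"hr"` or `"combined"`.
#' @param config a [forecast_config()].
#' @return object of class `pseudo_prospective` with hourly `times`,
#'   `likelihood`, `risk`, `provenance` (issue index per hour),
#'   `issue_times` and the evaluation `events` (training seizures
#'   excluded).
#' @export
run_pseudo_prospective <- function(hr, diary, initial_cutoff, end_time,
                                   modality = c("diary", "hr", "combined"),
                                   config = forecast_config()) {
  modality <- match.arg(modality)
  grid <- hourly_grid(initial_cutoff, end_time)
  if (length(grid) == 0) stopf("run_pseudo_prospective: empty evaluation span")
  lik <- rep(NA_real_, length(grid))
  risk <- rep(NA_character_, length(grid))
  prov <- rep(NA_integer_, length(grid))
  issue_times <- as.POSIXct(character(), tz = "UTC")
  t_issue <- initial_cutoff
  seg_i <- 0L
  log <- list()
  while (t_issue < end_time) {
    model <- train_forecaster(hr, diary, t_issue, config)
    seg <- issue_forecast(model, t_issue, config$horizon_days, modality)
    seg_i <- seg_i + 1L
    issue_times <- c(issue_times, t_issue)
    log[[seg_i]] <- list(issue_time = t_issue,
                         n_train_events = model$n_train_events,
                         flat = seg$flat)
    # next reissue: midnight after the next event, or 7 days, whichever first
    future_ev <- diary$times[diary$times >= t_issue]
    next_t <- t_issue + config$reissue_interval_days * SECS_PER_DAY
    if (length(future_ev) > 0) {
      ev_mid <- midnight_after(future_ev[1])
      if (ev_mid > t_issue && ev_mid < next_t) next_t <- ev_mid
    }
    # fill hours covered by this segment until the next issue
    upto <- min(next_t, end_time)
    sel <- which(grid >= t_issue & grid < upto)
    if (length(sel) > 0) {
      off <- round(as.numeric(difftime(grid[sel], t_issue, units = "hours"))) + 1L
      if (any(off > length(seg$times))) {
        stopf("run_pseudo_prospective: reissue gap exceeds the %g-day horizon",
              seg$horizon_days)
      }
      lik[sel] <- seg$likelihood[off]
      risk[sel] <- as.character(seg$risk[off])
      prov[sel] <- seg_i
    }
    t_issue <- next_t
  }
  events_eval <- event_diary(diary$times[diary$times >= initial_cutoff &
                                           diary$times < end_time])
  structure(list(times = grid, likelihood = lik,
                 risk = factor(risk, levels = c("low", "medium", "high")),
                 provenance = prov, issue_times = issue_times,
                 events = events_eval, modality = modality,
                 issue_log = log),
            class = "pseudo_prospective")
}

#' @export
print.pseudo_prospective <- function(x, ...) {
  cat(sprintf("<pseudo_prospective> %s: %d h (%.1f d), %d issues, %d events\n",
              x$modality, length(x$times), length(x$times) / 24,
              length(x$issue_times), length(x$events$times)))
  invisible(x)
}

#' Average an hourly forecast series to daily resolution
#'
#' Arithmetic mean of the 24 hourly likelihoods of each complete calendar
#' (UTC) day; partial first/last days are excluded with a warning.
#'
#' @param series a [run_pseudo_prospective()] result (or any list with
#'   hourly `times` and `likelihood`).
#' @return object of class `daily_forecast` with `dates`, `likelihood` and
#'   the events carried over from `series` (if any).
#' @export
daily_average <- function(series) {
  dates <- as.Date(series$times, tz = "UTC")
  counts <- table(dates)
  full <- names(counts)[counts == 24]
  if (length(full) < length(counts)) {
    warnf("daily_average: excluding %d partial day(s)",
          length(counts) - length(full))
  }
  keep <- dates %in% as.Date(full)
  daily <- tapply(series$likelihood[keep], as.character(dates[keep]), mean)
  structure(list(dates = as.Date(names(daily)),
                 likelihood = as.numeric(daily),
                 events = series$events),
            class = "daily_forecast")
}

#' Select the best modality by evaluation AUC
#'
#' Computes the time-in-warning AUC of each candidate pseudo-prospective
#' series against the evaluation events and returns the name of the best;
#' exact ties prefer fewer modalities (diary, then hr, then combined).
#'
#' @param series_by_modality named list of [run_pseudo_prospective()]
#'   results (names among `diary`, `hr`, `combined`).
#' @param events an [event_diary()] of evaluation events.
#' @return name of the selected modality (with the per-modality AUCs as
#'   attribute `auc`).
#' @export
select_best <- function(series_by_modality, events) {
  if (length(series_by_modality) == 0) stopf("select_best: no candidate series")
  auc <- vapply(series_by_modality, function(s) {
    roc_auc(s$likelihood, event_hour_mask(s$times, events))
  }, numeric(1))
  pref <- c("diary", "hr", "combined")
  nm <- names(auc)[order(-auc, match(names(auc), pref))][1]
  attr(nm, "auc") <- auc
  nm
}
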