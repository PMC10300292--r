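# Additive trend + Fourier-seasonality model used to project heart-rate
# cycles beyond the end of the record, and the fixed-sinusoid projection of
# seizure cycles.

#' Fit an additive model to a heart-rate series
#'
#' Penalised least-squares fit of
#' `y(t) = g(t) + s(t) + e(t)`
#' where `g` is a piecewise-linear trend (changepoints at 25 evenly spaced
#' candidates over the first 80% of the record) and `s` is a sum of Fourier
#' seasonal blocks, one per period:
#' `s(t) = sum_n a_n cos(2 pi n t / P) + b_n sin(2 pi n t / P)`.
#' The seasonal set is `{1, 7, 365.25}` days plus every detected
#' heart-rate cycle period; a default period is skipped when a detected
#' period lies within 10% of it (near-duplicate Fourier blocks are
#' collinear and corrupt the projected phase), and periods longer than the
#' record are dropped with a warning. Fourier order is 3 per daily/multidien term
#' and 10 for the yearly term. Fitting happens on the hourly-downsampled
#' (mean per hour) gap-filled series; an L2 penalty is applied to the
#' changepoint slope adjustments and the seasonal coefficients.
#'
#' @param hr a gap-filled [hr_series()].
#' @param periods detected cycle periods to add to the default seasonal
#'   set, days.
#' @param n_changepoints trend changepoint candidates (default 25).
#' @param seasonal_penalty,trend_penalty ridge penalties (default 1 and 10).
#' @return object of class `additive_model` with the trend and per-period
#'   Fourier coefficients, residual SD, and the fitting grid metadata.
#' @export
fit_additive <- function(hr, periods = numeric(0), n_changepoints = 25,
                         seasonal_penalty = 1, trend_penalty = 10) {
  if (anyNA(hr$bpm)) stopf("fit_additive: gap-fill the series first")
  # hourly means of the 5-min samples
  n5 <- length(hr$bpm)
  per_hour <- 3600 / hr$step_secs
  n_h <- floor(n5 / per_hour)
  y <- colMeans(matrix(hr$bpm[seq_len(n_h * per_hour)], nrow = per_hour))
  t_days <- (seq_len(n_h) - 1) / 24
  span <- n_h / 24
  periods <- sort(unique(round(periods, 6)))
  # default daily/weekly/yearly rhythms, skipping any that nearly coincides
  # with a detected period (near-duplicate Fourier blocks are collinear and
  # split the amplitude between beating terms)
  defaults <- c(1, 7, 365.25)
  defaults <- defaults[vapply(defaults, function(d)
    all(abs(log(periods / d)) > 0.1), logical(1))]
  all_periods <- sort(c(periods, defaults))
  drop <- all_periods > span
  if (any(drop)) {
    if (any(all_periods[drop] %in% periods)) {
      warnf("fit_additive: dropping seasonal period(s) longer than the record: %s d",
            paste(signif(intersect(all_periods[drop], periods), 4), collapse = ", "))
    }
    all_periods <- all_periods[!drop]
  }
  orders <- ifelse(all_periods >= 300, 10L, 3L)
  cps <- seq(0, 0.8 * span, length.out = n_changepoints + 1)[-1]
  X_trend <- cbind(1, t_days,
                   vapply(cps, function(c) pmax(0, t_days - c), numeric(n_h)))
  seas_blocks <- lapply(seq_along(all_periods), function(k) {
    P <- all_periods[k]
    do.call(cbind, lapply(seq_len(orders[k]), function(nn) {
      cbind(cos(2 * pi * nn * t_days / P), sin(2 * pi * nn * t_days / P))
    }))
  })
  X <- cbind(X_trend, do.call(cbind, seas_blocks))
  pen <- c(0, 0, rep(trend_penalty, length(cps)),
           rep(seasonal_penalty, sum(orders) * 2))
  beta <- solve(crossprod(X) + diag(pen), crossprod(X, y))
  fitted <- drop(X %*% beta)
  n_tr <- ncol(X_trend)
  offsets <- n_tr + c(0, cumsum(orders * 2))
  seasonal <- lapply(seq_along(all_periods), function(k) {
    coefs <- beta[(offsets[k] + 1):offsets[k + 1]]
    list(period = all_periods[k], order = orders[k],
         a = coefs[seq(1, length(coefs), 2)],
         b = coefs[seq(2, length(coefs), 2)])
  })
  structure(list(trend = list(intercept = beta[1], slope = beta[2],
                              changepoints = cps, deltas = beta[3:n_tr]),
                 seasonal = seasonal,
                 noise_sd = stats::sd(y - fitted),
                 start = hr$start, train_hours = n_h),
            class = "additive_model")
}

#' @export
print.additive_model <- function(x, ...) {
  amps <- vapply(x$seasonal, function(s) sqrt(s$a[1]^2 + s$b[1]^2), numeric(1))
  cat(sprintf("<additive_model> %d train hours, residual SD %.2f\n",
              x$train_hours, x$noise_sd))
  cat("  seasonal terms (fundamental amplitude):\n")
  for (i in seq_along(x$seasonal)) {
    cat(sprintf("    P = %7.2f d  order %2d  amp %.3f\n",
                x$seasonal[[i]]$period, x$seasonal[[i]]$order, amps[i]))
  }
  invisible(x)
}

# Evaluate one seasonal block of an additive model at times (days).
eval_seasonal <- function(term, t_days) {
  out <- numeric(length(t_days))
  for (nn in seq_len(term$order)) {
    w <- 2 * pi * nn * t_days / term$period
    out <- out + term$a[nn] * cos(w) + term$b[nn] * sin(w)
  }
  out
}

# Evaluate the piecewise-linear trend at times (days).
eval_trend <- function(trend, t_days) {
  out <- trend$intercept + trend$slope * t_days
  for (i in seq_along(trend$changepoints)) {
    out <- out + trend$deltas[i] * pmax(0, t_days - trend$changepoints[i])
  }
  out
}

#' Project a heart-rate cycle and its phase into the future
#'
#' Evaluates the additive model's seasonal block for the cycle's period over
#' the past-plus-future hourly grid, bandpasses it at the cycle's band (the
#' trend is held out of the phase computation), applies the same Hilbert
#' phase used for observed data, and returns the future segment. This keeps
#' the projected phase convention identical to the training phase.
#'
#' @param model a fitted [fit_additive()] model.
#' @param cycle a [cycle_spec()] whose period is among the model's seasonal
#'   terms.
#' @param horizon_days projection length, days (default 60).
#' @return list with `times` (future hourly grid), `value` (projected cycle
#'   signal), `phase` (a [phase_series()]) and a `degenerate` flag (zero
#'   amplitude); `horizon_days = 0` returns empty vectors.
#' @export
project_hr_cycle <- function(model, cycle, horizon_days = 60) {
  k <- which(vapply(model$seasonal, function(s)
    isTRUE(all.equal(s$period, cycle$period, tolerance = 1e-6)), logical(1)))
  if (length(k) == 0) {
    stopf("project_hr_cycle: period %.3g d is not a seasonal term of the model",
          cycle$period)
  }
  n_fut <- round(horizon_days * 24)
  issue <- model$start + 3600 * model$train_hours
  if (n_fut == 0) {
    return(list(times = issue[0], value = numeric(0),
                phase = phase_series(issue[0], numeric(0)), degenerate = FALSE))
  }
  # evaluate past the horizon so the Hilbert phase of the returned segment
  # is free of end-of-record edge distortion
  tail_h <- ceiling(2 * cycle$band_high * 24)
  n_all <- model$train_hours + n_fut + tail_h
  t_days <- (seq_len(n_all) - 1) / 24
  s <- eval_seasonal(model$seasonal[[k[1]]], t_days)
  degenerate <- stats::sd(s) < 1e-10
  if (!degenerate) {
    # bandpass on the hourly grid at the cycle band, reflection-padded
    f_nyq <- 12                              # cycles/day at hourly sampling
    bf <- signal::butter(2, c(1 / cycle$band_high, 1 / cycle$band_low) / f_nyq,
                         type = "pass")
    pad <- min(n_all - 1, ceiling(cycle$band_high * 24))
    sp <- c(rev(s[seq_len(pad)]), s, rev(s[n_all - seq_len(pad) + 1]))
    s <- signal::filtfilt(bf, sp)[pad + seq_len(n_all)]
  }
  fut <- model$train_hours + seq_len(n_fut)
  times <- issue + 3600 * (seq_len(n_fut) - 1)
  phases <- if (degenerate) numeric(n_fut) else {
    wrap_pi(Arg(analytic_signal(s)))[fut]
  }
  list(times = times, value = s[fut],
       phase = phase_series(times, phases),
       degenerate = degenerate)
}

#' Project a seizure cycle into the future
#'
#' Seizure cycles are fixed sinusoids, so projection is exact and
#' deterministic: the phase on the future hourly grid continues
#' `2 pi (t - reference_time) / period`.
#'
#' @param cycle a diary [cycle_spec()].
#' @param reference_time phase origin (training-record start).
#' @param issue_time forecast issue time (start of the future grid).
#' @param horizon_days projection length, days (default 60).
#' @return a [phase_series()] on the future hourly grid.
#' @export
project_event_cycle <- function(cycle, reference_time, issue_time,
                                horizon_days = 60) {
  if (cycle$source != "diary") {
    stopf("project_event_cycle: cycle source must be 'diary'")
  }
  n_fut <- round(horizon_days * 24)
  times <- issue_time + 3600 * (seq_len(n_fut) - 1)
  sinusoid_phase(times, cycle$period, reference_time)
}
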