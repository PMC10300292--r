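# Forecast scoring: time-in-warning ROC/AUC, operating point, Brier skill
# score, surrogate significance and the time-of-day baseline.

#' Event labels for a forecast grid
#'
#' Marks the forecast steps containing at least one event: hours at hourly
#' resolution, calendar days at daily resolution. Multiple events in one
#' step count once.
#'
#' @param times POSIXct hourly grid or Date vector (daily).
#' @param events an [event_diary()].
#' @return logical vector along `times`.
#' @export
event_labels <- function(times, events) {
  if (inherits(times, "Date")) {
    times %in% as.Date(events$times, tz = "UTC")
  } else {
    as.numeric(times) %in% as.numeric(unique(trunc(events$times, units = "hours")))
  }
}

#' Time-in-warning ROC AUC
#'
#' The ROC is the plot of time spent in high risk (fraction of all steps at
#' or above a warning threshold) against the true positive rate (fraction
#' of event steps at or above it), as the threshold sweeps the unique
#' likelihood values. The AUC is the trapezoidal area including the (0,0)
#' and (1,1) endpoints. A constant forecast scores 0.5; a forecast equal to
#' the event indicator approaches 1 as events become rare.
#'
#' @param likelihood numeric forecast series.
#' @param labels logical event labels (see [event_labels()]).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(likelihood, labels) {
  stopifnot(length(likelihood) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0) stopf("roc_auc: no event steps in the evaluation span")
  if (n_pos == length(labels)) stopf("roc_auc: no non-event steps in the evaluation span")
  ord <- order(likelihood, decreasing = TRUE)
  ls <- likelihood[ord]
  pos <- labels[ord]
  bounds <- cumsum(rle(ls)$lengths)     # last index of each unique value
  x <- c(0, bounds / length(ls))        # time fraction at/above threshold
  y <- c(0, cumsum(pos)[bounds] / n_pos)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sensitivity and time in high risk
#'
#' Sensitivity is the fraction of event steps labelled high risk; time in
#' high is the fraction of all steps labelled high risk.
#'
#' @param risk factor of risk labels (`low`/`medium`/`high`).
#' @param labels logical event labels on the same grid.
#' @return named numeric `c(sensitivity, time_in_high)`.
#' @export
operating_point <- function(risk, labels) {
  stopifnot(length(risk) == length(labels))
  high <- risk == "high"
  c(sensitivity = if (sum(labels) == 0) NA_real_ else mean(high[labels]),
    time_in_high = mean(high))
}

#' Brier skill score
#'
#' `BS` is the mean squared difference between the forecast likelihood and
#' the 0/1 event indicator; the skill score is `BSS = 1 - BS / BS_ref`
#' against a reference forecast, by default the constant series at the
#' evaluation-period mean event rate. BSS = 1 for a perfect forecast and 0
#' for no improvement over the reference.
#'
#' @param likelihood numeric forecast series.
#' @param labels logical event labels.
#' @param reference reference forecast series (default: constant mean event
#'   rate).
#' @return BSS (<= 1).
#' @export
brier_skill_score <- function(likelihood, labels, reference = NULL) {
  stopifnot(length(likelihood) == length(labels))
  outcome <- as.numeric(labels)
  if (is.null(reference)) reference <- rep(mean(outcome), length(outcome))
  bs <- mean((likelihood - outcome)^2)
  bs_ref <- mean((reference - outcome)^2)
  if (bs_ref == 0) stopf("brier_skill_score: reference forecast has zero Brier score")
  1 - bs / bs_ref
}

#' Surrogate significance test for forecast AUC
#'
#' Randomly relocates the observed number of event steps uniformly (without
#' replacement) over the evaluation grid, recomputes the time-in-warning
#' AUC each time (200 shuffles by default), and declares the forecast
#' significant when the observed AUC exceeds the 95th percentile of the
#' surrogate AUC distribution (p < 0.05). The reported p-value uses the
#' add-one permutation convention `p = (1 + #\{surrogate >= observed\}) /
#' (n_shuffles + 1)`.
#'
#' @param likelihood numeric forecast series.
#' @param labels logical event labels.
#' @param n_shuffles surrogate draws (default 200).
#' @param seed optional integer seed for the shuffles.
#' @param significance confidence level (default 0.95).
#' @return list with `observed_auc`, `surrogate_auc`, `p_value`,
#'   `significant`.
#' @export
surrogate_test <- function(likelihood, labels, n_shuffles = 200, seed = NULL,
                           significance = 0.95) {
  n <- length(likelihood)
  n_pos <- sum(labels)
  if (n_pos > n) stopf("surrogate_test: more events than steps")
  observed <- roc_auc(likelihood, labels)
  surr <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    lab <- logical(n)
    lab[sample.int(n, n_pos)] <- TRUE
    roc_auc(likelihood, lab)
  }, numeric(1)))
  list(observed_auc = observed, surrogate_auc = surr,
       p_value = (1 + sum(surr >= observed)) / (n_shuffles + 1),
       significant = observed > stats::quantile(surr, significance, names = FALSE))
}

#' Time-of-day baseline forecast
#'
#' Uses only clock time: the hourly likelihood is the number of training
#' events reported in that clock hour divided by the number of training
#' days, repeating every 24 hours. Averaged to daily resolution it is
#' constant, i.e. chance level.
#'
#' @param train_events an [event_diary()] of training events.
#' @param evaluation_times POSIXct hourly grid to forecast on.
#' @param training_days number of days in the training window; defaults to
#'   the (whole-day) span of the training events.
#' @return numeric likelihood series along `evaluation_times`.
#' @export
time_of_day_baseline <- function(train_events, evaluation_times,
                                 training_days = NULL) {
  if (length(train_events$times) == 0) {
    stopf("time_of_day_baseline: no training events")
  }
  if (is.null(training_days)) {
    day0 <- as.POSIXct(trunc(min(train_events$times), units = "days"), tz = "UTC")
    training_days <- max(1, ceiling(time_days(max(train_events$times), day0)))
  }
  hour_of <- function(t) as.integer(format(t, "%H", tz = "UTC"))
  counts <- tabulate(hour_of(train_events$times) + 1L, 24L)
  (counts / training_days)[hour_of(evaluation_times) + 1L]
}

#' Evaluate a pseudo-prospective forecast
#'
#' Bundles the scoring used for each modality and resolution: AUC,
#' sensitivity and time-in-high at the fitted thresholds (hourly only),
#' Brier skill score, and the surrogate significance test.
#'
#' @param series a [run_pseudo_prospective()] or [daily_average()] result.
#' @param n_shuffles surrogate draws (default 200).
#' @param seed optional seed for the surrogate shuffles.
#' @return object of class `evaluation_report`.
#' @export
evaluate_forecast <- function(series, n_shuffles = 200, seed = NULL) {
  daily <- inherits(series, "daily_forecast")
  grid <- if (daily) series$dates else series$times
  labels <- event_labels(grid, series$events)
  st <- surrogate_test(series$likelihood, labels, n_shuffles, seed)
  op <- if (!daily && !is.null(series$risk)) {
    operating_point(series$risk, labels)
  } else c(sensitivity = NA_real_, time_in_high = NA_real_)
  structure(list(auc = st$observed_auc,
                 sensitivity = op[["sensitivity"]],
                 time_in_high = op[["time_in_high"]],
                 bss = brier_skill_score(series$likelihood, labels),
                 surrogate_p = st$p_value,
                 significant = st$significant,
                 n_events = sum(labels),
                 resolution = if (daily) "daily" else "hourly"),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: AUC %.3f%s, BSS %.3f, p %.3f\n",
              x$resolution, x$auc,
              if (x$significant) " (above chance)" else "", x$bss,
              x$surrogate_p))
  if (is.finite(x$sensitivity)) {
    cat(sprintf("  sensitivity %.0f%%, time in high %.0f%% over %d event steps\n",
                100 * x$sensitivity, 100 * x$time_in_high, x$n_events))
  }
  invisible(x)
}
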