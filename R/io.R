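# CSV readers/writers, model serialisation, run configuration and the
# end-to-end pipeline driver.

#' Read a heart-rate CSV
#'
#' Expects a header `timestamp,bpm` with ISO-8601 UTC timestamps
#' (`YYYY-MM-DDTHH:MM:SSZ`). Values are snapped to the 5-minute grid
#' spanning the file; duplicate grid slots are averaged with a warning,
#' empty `bpm` fields and absent grid slots become missing samples.
#'
#' @param path file path.
#' @return an [hr_series()].
#' @export
read_hr_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), c("timestamp", "bpm"))) {
    stopf("read_hr_csv: expected header 'timestamp,bpm' in %s", path)
  }
  ts <- parse_iso(df$timestamp)
  if (anyNA(ts)) {
    stopf("read_hr_csv: unparseable timestamp at line %d of %s",
          which(is.na(ts))[1] + 1L, path)
  }
  bpm <- suppressWarnings(as.numeric(df$bpm))
  bad <- is.na(bpm) & nzchar(trimws(df$bpm))
  if (any(bad)) {
    stopf("read_hr_csv: unparseable bpm at line %d of %s",
          which(bad)[1] + 1L, path)
  }
  if (length(ts) == 0) stopf("read_hr_csv: empty file %s", path)
  start <- as.POSIXct(floor(as.numeric(min(ts)) / HR_STEP_SECS) * HR_STEP_SECS,
                      origin = "1970-01-01", tz = "UTC")
  slot <- round(as.numeric(difftime(ts, start, units = "secs")) / HR_STEP_SECS) + 1L
  n <- max(slot)
  if (anyDuplicated(slot)) {
    warnf("read_hr_csv: %d duplicate grid slot(s) averaged",
          sum(duplicated(slot)))
  }
  vals <- rep(NA_real_, n)
  agg <- tapply(bpm, slot, function(v) mean(v, na.rm = TRUE))
  agg[is.nan(agg)] <- NA_real_
  vals[as.integer(names(agg))] <- agg
  hr_series(start, vals)
}

#' Write a heart-rate CSV
#'
#' Inverse of [read_hr_csv()]: `timestamp,bpm` rows for every grid slot,
#' with an empty field for missing samples.
#'
#' @param hr an [hr_series()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hr_csv <- function(hr, path) {
  bpm <- ifelse(hr$missing, "", formatC(hr$bpm, format = "fg", digits = 10))
  utils::write.csv(data.frame(timestamp = format_iso(hr_times(hr)), bpm = bpm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event-diary CSV
#'
#' Expects a header `timestamp` (ISO-8601 UTC). Rows are sorted; exact
#' duplicates are retained (same-day or same-minute repeat seizures are
#' legitimate).
#'
#' @param path file path.
#' @return an [event_diary()].
#' @export
read_diary_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), "timestamp")) {
    stopf("read_diary_csv: expected header 'timestamp' in %s", path)
  }
  if (nrow(df) == 0) return(event_diary())
  ts <- parse_iso(df$timestamp)
  if (anyNA(ts)) {
    stopf("read_diary_csv: unparseable timestamp at line %d of %s",
          which(is.na(ts))[1] + 1L, path)
  }
  event_diary(ts)
}

#' Write an event-diary CSV
#'
#' @param diary an [event_diary()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_diary_csv <- function(diary, path) {
  utils::write.csv(data.frame(timestamp = format_iso(diary$times)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- model serialisation ----------------------------------------------------

serialize_cycle <- function(cy) {
  list(source = cy$source, period = cy$period, band_low = cy$band_low,
       band_high = cy$band_high, si = cy$si, power = cy$power)
}

serialize_modality <- function(m) {
  if (is.null(m)) return(NULL)
  out <- list(flat = m$flat, rate = m$rate,
              cycles = lapply(m$cycles, serialize_cycle),
              bin_likelihoods = lapply(m$binlik, function(b) b$p),
              thresholds = m$thresholds[c("medium_cutoff", "high_cutoff",
                                          "strict", "degenerate")])
  if (!is.null(m$additive)) {
    a <- m$additive
    out$additive <- list(trend = a$trend, seasonal = a$seasonal,
                         noise_sd = a$noise_sd, start = format_iso(a$start),
                         train_hours = a$train_hours)
    out$training_mean <- m$training_mean
  }
  out
}

#' Serialise a trained forecaster to JSON
#'
#' Stores cycles, bin edges/likelihoods, thresholds and the additive
#' projection model so a forecast can be reissued without refitting (the
#' training likelihood series itself is not needed for issuance and is not
#' stored).
#'
#' @param model a [train_forecaster()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    package = "cyclecast",
    version = as.character(utils::packageVersion("cyclecast")),
    origin = format_iso(model$origin),
    cutoff = format_iso(model$cutoff),
    n_train_events = model$n_train_events,
    config = unclass(model$config),
    bin_edges = seq(-pi, pi, length.out = model$config$n_bins + 1),
    diary = serialize_modality(model$diary),
    hr = serialize_modality(model$hr),
    combined = if (is.null(model$combined)) NULL else
      list(thresholds = model$combined$thresholds[c("medium_cutoff",
                                                    "high_cutoff", "strict",
                                                    "degenerate")])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

deserialize_modality <- function(m, n_bins) {
  if (is.null(m)) return(NULL)
  out <- list(
    flat = m$flat, rate = m$rate,
    cycles = lapply(m$cycles, function(cy) {
      cycle_spec(cy$source, cy$period,
                 band_low = if (is.null(cy$band_low)) NA_real_ else cy$band_low,
                 band_high = if (is.null(cy$band_high)) NA_real_ else cy$band_high,
                 si = if (is.null(cy$si)) NA_real_ else cy$si,
                 power = if (is.null(cy$power)) NA_real_ else cy$power)
    }),
    binlik = lapply(m$bin_likelihoods, function(p) {
      structure(list(p = as.numeric(p), n_bins = length(p)),
                class = "bin_likelihood")
    }),
    thresholds = structure(m$thresholds, class = "risk_thresholds")
  )
  if (!is.null(m$additive)) {
    a <- m$additive
    out$additive <- structure(
      list(trend = lapply(a$trend, unlist),
           seasonal = lapply(a$seasonal, function(s)
             list(period = s$period, order = s$order,
                  a = as.numeric(unlist(s$a)), b = as.numeric(unlist(s$b)))),
           noise_sd = a$noise_sd, start = parse_iso(a$start),
           train_hours = a$train_hours),
      class = "additive_model")
    out$training_mean <- m$training_mean
  }
  out
}

#' Restore a forecaster from JSON
#'
#' @param path a file written by [write_model_json()].
#' @return a `cycle_forecaster` able to [issue_forecast()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- do.call(forecast_config, obj$config)
  structure(list(origin = parse_iso(obj$origin), cutoff = parse_iso(obj$cutoff),
                 config = cfg, n_train_events = obj$n_train_events,
                 diary = deserialize_modality(obj$diary, cfg$n_bins),
                 hr = deserialize_modality(obj$hr, cfg$n_bins),
                 combined = if (is.null(obj$combined)) NULL else
                   list(thresholds = structure(obj$combined$thresholds,
                                               class = "risk_thresholds"))),
            class = "cycle_forecaster")
}

# --- run configuration ------------------------------------------------------

#' Pipeline run configuration
#'
#' Paths plus the forecasting constants (all overridable, defaults as in
#' [forecast_config()]).
#'
#' @param hr_csv,diary_csv input paths (`hr_csv` may be `NULL` for a
#'   diary-only run).
#' @param out_dir output directory.
#' @param modalities modalities to run.
#' @param end_time optional POSIXct end of the evaluation span; defaults to
#'   the end of the heart-rate record (or last event midnight).
#' @param seed integer seed (surrogate shuffles).
#' @inheritParams forecast_config
#' @return a list of class `run_config`.
#' @export
run_config <- function(hr_csv = NULL, diary_csv, out_dir,
                       modalities = c("diary", "hr", "combined"),
                       si_threshold = 0.3, n_bins = 18, horizon_days = 60,
                       reissue_interval_days = 7, n_training_events = 10,
                       surrogates = 200, significance = 0.95,
                       end_time = NULL, seed = 1L) {
  fc <- forecast_config(si_threshold, n_bins, horizon_days,
                        reissue_interval_days, n_training_events, surrogates,
                        significance)
  modalities <- match.arg(modalities, several.ok = TRUE)
  structure(c(list(hr_csv = hr_csv, diary_csv = diary_csv, out_dir = out_dir,
                   modalities = modalities, end_time = end_time,
                   seed = as.integer(seed)),
              unclass(fc)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$end_time)) y$end_time <- parse_iso(y$end_time)
  do.call(run_config, y)
}

#' Run the forecasting pipeline end to end
#'
#' Reads the inputs, walks the pseudo-prospective schedule for every
#' requested modality, averages to daily resolution, evaluates everything
#' (AUC, BSS, sensitivity/time-in-high, surrogate significance), selects
#' the best modality by AUC and writes all artifacts into `out_dir`:
#' `cycles.json`, `model.json` (final retraining), hourly and daily
#' forecast CSVs per modality, `evaluation.json` and an issuance log
#' `issues.jsonl`.
#'
#' @param config a [run_config()].
#' @return invisibly, the evaluation summary list.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("run_pipeline [%s]: %s", name, conditionMessage(e))
    })
  }
  diary <- stage("read", read_diary_csv(config$diary_csv))
  hr <- if (!is.null(config$hr_csv)) stage("read", read_hr_csv(config$hr_csv)) else NULL
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fc <- forecast_config(config$si_threshold, config$n_bins,
                        config$horizon_days, config$reissue_interval_days,
                        config$n_training_events, config$surrogates,
                        config$significance)
  cut0 <- stage("train", initial_cutoff(diary, fc$n_training_events))
  end_time <- config$end_time
  if (is.null(end_time)) {
    end_time <- if (!is.null(hr)) {
      as.POSIXct(trunc(hr_end(hr), units = "days"), tz = "UTC")
    } else {
      midnight_after(max(diary$times))
    }
  }
  modalities <- config$modalities
  if (is.null(hr)) modalities <- intersect(modalities, "diary")

  runs <- list(); evals <- list()
  for (mod in modalities) {
    pp <- stage(mod, run_pseudo_prospective(hr, diary, cut0, end_time,
                                            modality = mod, config = fc))
    dd <- suppressWarnings(daily_average(pp))
    runs[[mod]] <- pp
    evals[[mod]] <- list(
      hourly = unclass(evaluate_forecast(pp, fc$surrogates, config$seed)),
      daily = unclass(evaluate_forecast(dd, fc$surrogates, config$seed + 1L)))
    utils::write.csv(data.frame(timestamp = format_iso(pp$times),
                                likelihood = pp$likelihood,
                                risk = as.character(pp$risk)),
                     file.path(config$out_dir, sprintf("forecast_hourly_%s.csv", mod)),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(date = as.character(dd$dates),
                                likelihood = dd$likelihood),
                     file.path(config$out_dir, sprintf("forecast_daily_%s.csv", mod)),
                     row.names = FALSE, quote = FALSE)
  }
  best <- stage("select", select_best(runs, runs[[1]]$events))

  final <- stage("train", train_forecaster(hr, diary,
                                           max(cut0, min(end_time, midnight_after(max(diary$times)))),
                                           fc))
  write_model_json(final, file.path(config$out_dir, "model.json"))
  all_cycles <- c(lapply(final$diary$cycles, serialize_cycle),
                  if (!is.null(final$hr)) lapply(final$hr$cycles, serialize_cycle))
  jsonlite::write_json(all_cycles, file.path(config$out_dir, "cycles.json"),
                       auto_unbox = TRUE, digits = NA)

  # fingerprint the analysis parameters (not the filesystem paths)
  params <- unclass(config)[setdiff(names(config),
                                    c("hr_csv", "diary_csv", "out_dir"))]
  cfg_str <- jsonlite::toJSON(params[!vapply(params, is.null, logical(1))],
                              auto_unbox = TRUE, force = TRUE)
  summary <- list(
    config_hash = config_hash(as.character(cfg_str)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cyclecast")),
    initial_cutoff = format_iso(cut0),
    end_time = format_iso(end_time),
    n_evaluation_events = length(runs[[1]]$events$times),
    best_modality = as.character(best),
    auc = as.list(attr(best, "auc")),
    evaluation = evals
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- vapply(runs[[1]]$issue_log, function(l) {
    as.character(jsonlite::toJSON(list(issue_time = format_iso(l$issue_time),
                                       n_train_events = l$n_train_events,
                                       flat = l$flat), auto_unbox = TRUE))
  }, character(1))
  writeLines(log_lines, file.path(config$out_dir, "issues.jsonl"))
  invisible(summary)
}
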