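#' Heart-rate series on a uniform 5-minute grid
#'
#' Container for a wearable heart-rate recording resampled to the 5-minute
#' grid used throughout the pipeline. Missing samples (device non-wear) are
#' `NA` in `bpm` and flagged in `missing`; after gap filling the values are
#' imputed but the mask is retained.
#'
#' @param start POSIXct (UTC) timestamp of the first grid slot.
#' @param bpm numeric vector of beats-per-minute values; `NA` where missing.
#' @param missing optional logical mask; defaults to `is.na(bpm)`.
#' @return an object of class `hr_series` with fields `start`, `step_secs`
#'   (always 300), `bpm` and `missing`.
#' @export
#' @examples
#' hr <- hr_series(as.POSIXct("2020-01-01", tz = "UTC"), bpm = rep(70, 288))
#' hr
hr_series <- function(start, bpm, missing = is.na(bpm)) {
  if (!inherits(start, "POSIXct") || length(start) != 1L) {
    stopf("hr_series: 'start' must be a single POSIXct timestamp")
  }
  bpm <- as.numeric(bpm)
  missing <- as.logical(missing)
  if (length(missing) != length(bpm)) {
    stopf("hr_series: 'missing' mask length (%d) != values length (%d)",
          length(missing), length(bpm))
  }
  if (any(!is.finite(bpm) & !missing)) {
    stopf("hr_series: non-finite bpm values outside the missing mask")
  }
  structure(
    list(start = as.POSIXct(start, tz = "UTC"), step_secs = HR_STEP_SECS,
         bpm = bpm, missing = missing),
    class = "hr_series"
  )
}

#' @export
print.hr_series <- function(x, ...) {
  n <- length(x$bpm)
  cat(sprintf("<hr_series> %d samples @ 5 min (%.1f days) from %s\n",
              n, n * x$step_secs / SECS_PER_DAY, format_iso(x$start)))
  cat(sprintf("  missing: %.1f%%  mean bpm (observed): %.1f\n",
              100 * mean(x$missing),
              if (all(x$missing)) NA_real_ else mean(x$bpm[!x$missing], na.rm = TRUE)))
  invisible(x)
}

#' @export
length.hr_series <- function(x) length(x$bpm)

# POSIXct timestamps of every grid slot.
hr_times <- function(hr) {
  hr$start + hr$step_secs * (seq_along(hr$bpm) - 1)
}

# End of the recording span (exclusive).
hr_end <- function(hr) {
  hr$start + hr$step_secs * length(hr$bpm)
}

# Restrict an hr_series to samples strictly before `cutoff`.
hr_window <- function(hr, cutoff) {
  n <- floor(as.numeric(difftime(cutoff, hr$start, units = "secs")) / hr$step_secs)
  n <- max(0L, min(length(hr$bpm), n))
  if (n == 0L) stopf("hr_window: no heart-rate samples before %s", format_iso(cutoff))
  hr_series(hr$start, hr$bpm[seq_len(n)], hr$missing[seq_len(n)])
}

#' Event diary of self-reported seizure times
#'
#' An ordered list of event timestamps. Exact duplicates are retained:
#' multiple reported seizures in the same minute are real occurrences in
#' self-reported diaries.
#'
#' @param times POSIXct vector of event times (any order; sorted on input).
#' @return an object of class `event_diary`.
#' @export
event_diary <- function(times = as.POSIXct(character(), tz = "UTC")) {
  if (!inherits(times, "POSIXct")) stopf("event_diary: 'times' must be POSIXct")
  structure(list(times = sort(as.POSIXct(times, tz = "UTC"))),
            class = "event_diary")
}

#' @export
print.event_diary <- function(x, ...) {
  n <- length(x$times)
  if (n == 0) {
    cat("<event_diary> empty\n")
  } else {
    cat(sprintf("<event_diary> %d events, %s .. %s\n", n,
                format_iso(min(x$times)), format_iso(max(x$times))))
  }
  invisible(x)
}

#' @export
length.event_diary <- function(x) length(x$times)

# Events strictly before a cut-off.
diary_window <- function(diary, cutoff) {
  event_diary(diary$times[diary$times < cutoff])
}

#' Phase series on an hourly grid
#'
#' Instantaneous phase of one cycle, sampled hourly, wrapped to (-pi, pi].
#'
#' @param times POSIXct hourly grid.
#' @param phase numeric phases in radians, same length as `times`.
#' @return an object of class `phase_series`.
#' @export
phase_series <- function(times, phase) {
  if (length(times) != length(phase)) {
    stopf("phase_series: times and phase lengths differ")
  }
  phase <- as.numeric(phase)
  if (any(!is.finite(phase))) stopf("phase_series: non-finite phases")
  if (any(phase <= -pi | phase > pi)) {
    stopf("phase_series: phases must lie in (-pi, pi]")
  }
  structure(list(times = times, phase = phase), class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d hourly samples\n", length(x$phase)))
  invisible(x)
}

#' One detected cycle
#'
#' @param source `"hr"` or `"diary"`.
#' @param period cycle period in days.
#' @param band_low,band_high bandpass edges in days (heart-rate cycles).
#' @param si synchronization index of event phases on this cycle, in `[0, 1]`.
#' @param power time-averaged wavelet power at the cycle period (heart-rate
#'   cycles).
#' @return an object of class `cycle_spec`.
#' @export
cycle_spec <- function(source, period, band_low = NA_real_, band_high = NA_real_,
                       si = NA_real_, power = NA_real_) {
  source <- match.arg(source, c("hr", "diary"))
  if (!is.finite(period) || period <= 0) stopf("cycle_spec: period must be > 0")
  if (source == "hr") {
    if (!(is.finite(band_low) && is.finite(band_high) &&
          band_low > 0 && band_low < period && period < band_high)) {
      stopf("cycle_spec: need 0 < band_low < period < band_high for hr cycles")
    }
  }
  if (is.finite(si) && (si < 0 || si > 1)) stopf("cycle_spec: si must be in [0, 1]")
  structure(list(source = source, period = period, band_low = band_low,
                 band_high = band_high, si = si, power = power),
            class = "cycle_spec")
}

#' @export
print.cycle_spec <- function(x, ...) {
  extras <- c(
    if (is.finite(x$si)) sprintf("SI=%.3f", x$si),
    if (is.finite(x$power)) sprintf("power=%.3g", x$power),
    if (is.finite(x$band_low)) sprintf("band=[%.2f, %.2f] d", x$band_low, x$band_high)
  )
  cat(sprintf("<cycle_spec> %s %.1f d  %s\n", x$source, x$period,
              paste(extras, collapse = "  ")))
  invisible(x)
}
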