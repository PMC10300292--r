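# Phase-binned seizure likelihood models and their combination.

N_PHASE_BINS <- 18L
ODDS_EPS <- 1e-4   # clip likelihoods before the odds transform

# Bin index in 1..n_bins for phases in (-pi, pi]; bin b covers
# (edge_b, edge_{b+1}] so the partition is exact. A 1e-9 guard keeps phases
# computed along different arithmetic paths from straddling a bin edge by
# floating-point jitter.
phase_bin <- function(phase, n_bins = N_PHASE_BINS) {
  b <- ceiling((phase + pi) / (2 * pi / n_bins) - 1e-9)
  pmin(pmax(b, 1L), as.integer(n_bins))
}

#' Per-bin seizure likelihoods for one cycle
#'
#' The cycle phase interval (-pi, pi] is divided into `n_bins` equal bins
#' (18 by default). The likelihood of bin b is the number of seizure hours
#' whose phase fell in b divided by the number of hours bin b presented in
#' the cycle over the training record. Bins never visited get likelihood 0.
#' An hour containing one or more events counts once.
#'
#' @param phase a [phase_series()] on the hourly training grid.
#' @param events an [event_diary()] whose (floored-to-hour) times are
#'   covered by `phase$times`.
#' @param n_bins number of phase bins (default 18).
#' @return object of class `bin_likelihood`: list with `p` (length
#'   `n_bins`), `event_counts`, `visit_counts`, `n_bins` and a
#'   `no_events` flag.
#' @export
estimate_bin_likelihoods <- function(phase, events, n_bins = N_PHASE_BINS) {
  n_bins <- as.integer(n_bins)
  bins <- phase_bin(phase$phase, n_bins)
  visits <- tabulate(bins, n_bins)
  ev_hours <- unique(trunc(events$times, units = "hours"))
  no_events <- length(ev_hours) == 0
  if (no_events) {
    warnf("estimate_bin_likelihoods: no events in the training window; all-zero model")
    ev_counts <- integer(n_bins)
  } else {
    idx <- match(as.numeric(ev_hours), as.numeric(phase$times))
    if (anyNA(idx)) stopf("estimate_bin_likelihoods: %d event hour(s) outside the phase grid",
                          sum(is.na(idx)))
    ev_counts <- tabulate(bins[idx], n_bins)
  }
  p <- ifelse(visits > 0, ev_counts / visits, 0)
  structure(list(p = p, event_counts = ev_counts, visit_counts = visits,
                 n_bins = n_bins, no_events = no_events),
            class = "bin_likelihood")
}

#' @export
print.bin_likelihood <- function(x, ...) {
  cat(sprintf("<bin_likelihood> %d bins, %d event hours, peak bin %d (p=%.3g)\n",
              x$n_bins, sum(x$event_counts), which.max(x$p), max(x$p)))
  invisible(x)
}

#' Combine likelihoods across cycles with the logit model
#'
#' Likelihoods from different cycles (or data modalities) are combined via
#' the geometric mean of their odds:
#' `p = prod(p_i / (1 - p_i))^(1/n)`, `p_s = p / (1 + p)`.
#' The combination is order-invariant, idempotent for equal inputs and
#' monotone in every argument. Inputs are clipped into
#' `[1e-4, 1 - 1e-4]` first, since empty or always-hit bins would give zero
#' or infinite odds.
#'
#' @param p_list numeric vector (or list of equal-length numeric vectors,
#'   combined elementwise) of likelihoods.
#' @return combined likelihood(s) in (0, 1).
#' @export
#' @examples
#' combine_likelihoods(c(0.5, 0.8))  # 2/3
combine_likelihoods <- function(p_list) {
  if (is.list(p_list)) p_list <- do.call(rbind, p_list)
  if (length(p_list) == 0) stopf("combine_likelihoods: empty likelihood list")
  p <- pmin(pmax(p_list, ODDS_EPS), 1 - ODDS_EPS)
  if (is.matrix(p)) {
    log_odds <- colMeans(log(p / (1 - p)))
  } else {
    log_odds <- mean(log(p / (1 - p)))
  }
  stats::plogis(log_odds)
}

#' Fit medium/high risk thresholds
#'
#' Grid search over pairs of candidate cutoffs (the deduplicated percentiles
#' of the training likelihood series) for the two ordering criteria: (1)
#' seizures in high risk > seizures in medium risk > seizures in low risk;
#' (2) time in low risk > time in high risk. Criterion 2 is optimised after
#' criterion 1: among pairs satisfying (1), the pair maximising
#' `time_low - time_high` wins (ties prefer lower time-in-high). If no pair
#' satisfies the strict criterion 1, non-strict ordering is allowed and
#' flagged; if even that fails, degenerate all-low thresholds are returned
#' with a warning.
#'
#' @param likelihood numeric training likelihood series (hourly).
#' @param event_steps logical vector marking seizure hours, same length.
#' @param n_quantiles number of candidate percentiles (default 100).
#' @return object of class `risk_thresholds`: `medium_cutoff`,
#'   `high_cutoff`, `strict` (criterion-1 strictness achieved) and
#'   `degenerate` flags.
#' @export
fit_thresholds <- function(likelihood, event_steps, n_quantiles = 100) {
  stopifnot(length(likelihood) == length(event_steps))
  cand <- sort(unique(stats::quantile(likelihood,
                                      probs = seq(0, 1, length.out = n_quantiles),
                                      names = FALSE, type = 7)))
  if (length(cand) == 1) {
    warnf("fit_thresholds: constant likelihood series; degenerate all-low thresholds")
    return(structure(list(medium_cutoff = cand + 1, high_cutoff = cand + 1,
                          strict = FALSE, degenerate = TRUE),
                     class = "risk_thresholds"))
  }
  n <- length(likelihood)
  n_ev <- sum(event_steps)
  # per-candidate tail counts: steps / events with likelihood >= candidate
  t_ge <- vapply(cand, function(c) sum(likelihood >= c), numeric(1)) / n
  e_ge <- vapply(cand, function(c) sum(event_steps & likelihood >= c), numeric(1))
  pairs <- which(upper.tri(matrix(0, length(cand), length(cand)), diag = FALSE),
                 arr.ind = TRUE)
  m_i <- pairs[, 1]; h_i <- pairs[, 2]          # medium index < high index
  eh <- e_ge[h_i]
  em <- e_ge[m_i] - e_ge[h_i]
  el <- n_ev - e_ge[m_i]
  th <- t_ge[h_i]
  tl <- 1 - t_ge[m_i]
  pick <- function(ok) {
    if (!any(ok)) return(NULL)
    score <- tl - th
    score[!ok] <- -Inf
    best <- which(score == max(score))
    best[which.min(th[best])]
  }
  strict_ok <- eh > em & em > el
  sel <- pick(strict_ok & tl > th)
  strict <- TRUE
  if (is.null(sel)) sel <- pick(strict_ok)
  if (is.null(sel)) {
    strict <- FALSE
    relaxed_ok <- eh >= em & em >= el & eh > 0
    sel <- pick(relaxed_ok & tl > th)
    if (is.null(sel)) sel <- pick(relaxed_ok)
  }
  if (is.null(sel)) {
    warnf("fit_thresholds: no threshold pair orders the events; degenerate all-low thresholds")
    top <- max(likelihood)
    return(structure(list(medium_cutoff = top + 1, high_cutoff = top + 1,
                          strict = FALSE, degenerate = TRUE),
                     class = "risk_thresholds"))
  }
  structure(list(medium_cutoff = cand[m_i[sel]], high_cutoff = cand[h_i[sel]],
                 strict = strict, degenerate = FALSE),
            class = "risk_thresholds")
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat(sprintf("<risk_thresholds> medium >= %.4g, high >= %.4g%s%s\n",
              x$medium_cutoff, x$high_cutoff,
              if (!x$strict) " (non-strict ordering)" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Classify likelihoods into risk levels
#'
#' Low below the medium cutoff, medium in `[medium_cutoff, high_cutoff)`,
#' high at or above the high cutoff.
#'
#' @param likelihood numeric vector of likelihoods.
#' @param thresholds a [fit_thresholds()] result.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
classify_risk <- function(likelihood, thresholds) {
  lab <- rep("low", length(likelihood))
  lab[likelihood >= thresholds$medium_cutoff] <- "medium"
  lab[likelihood >= thresholds$high_cutoff] <- "high"
  factor(lab, levels = c("low", "medium", "high"))
}
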