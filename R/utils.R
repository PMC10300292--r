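# Internal helpers shared across the package.

SECS_PER_DAY <- 86400
HR_STEP_SECS <- 300L

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @keywords internal
#' @noRd
wrap_pi <- function(x) {
  m <- x %% (2 * pi)
  m[m > pi] <- m[m > pi] - 2 * pi
  m
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Time differences in fractional days relative to an origin timestamp.
time_days <- function(t, origin) {
  as.numeric(difftime(t, origin, units = "days"))
}

# Hourly POSIXct grid covering [from, to) (hour-aligned `from` expected).
hourly_grid <- function(from, to) {
  n <- floor(as.numeric(difftime(to, from, units = "hours")))
  if (n <= 0) return(from[0])
  from + 3600 * (seq_len(n) - 1)
}

# Midnight (UTC) strictly after time `t`: the training cut-off convention for
# a seizure reported at `t` is midnight ending that calendar day.
midnight_after <- function(t) {
  as.POSIXct(trunc(t, units = "days"), tz = "UTC") + SECS_PER_DAY
}

format_iso <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_iso <- function(x) {
  as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Small non-cryptographic polynomial string hash used to fingerprint run
# configurations in logs (not security-relevant).
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
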