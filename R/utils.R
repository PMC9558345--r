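# Internal helpers shared across modules.

#' Derive a child seed from a parent seed and a stream index
#'
#' All stochastic operations take a single integer seed; sub-streams (one per
#' animal, per replicate, ...) are split off deterministically so that modules
#' can be re-run independently without sharing global RNG state.
#'
#' @param seed integer parent seed.
#' @param i integer stream index (>= 0).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
split_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(i))
  # Lehmer-style mix kept inside 32-bit signed range via double arithmetic
  m <- 2147483647
  s <- (abs(seed) %% m) + 1
  for (k in c(i + 1, 7919)) {
    s <- (s * 48271 + k) %% m
  }
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles to (-pi, pi]
#' @param theta numeric vector of angles in radians.
#' @return wrapped angles.
#' @keywords internal
wrap_angle <- function(theta) {
  out <- ((theta + pi) %% (2 * pi)) - pi
  out[out == -pi] <- pi
  out
}

# Reflect coordinates into [lo, hi] (triangle-wave fold). Used by the
# simulators to keep correlated random walks on the landscape.
fold_coord <- function(z, lo, hi) {
  L <- hi - lo
  m <- (z - lo) %% (2 * L)
  lo + ifelse(m > L, 2 * L - m, m)
}

# day-of-year as a real number (fractional days since Jan 1, 00:00 UTC)
doy_frac <- function(t) {
  jan1 <- as.POSIXct(paste0(format(t, "%Y", tz = "UTC"), "-01-01"),
                     tz = "UTC")
  as.numeric(difftime(t, jan1, units = "days")) + 1
}

#' Julian week of a timestamp
#'
#' Week 1 covers days 1-7 of the calendar year, week 2 days 8-14, and so on
#' (weeks elapsed since January 1).
#'
#' @param t POSIXct vector.
#' @return integer vector of week indices.
#' @export
julian_week <- function(t) {
  doy <- as.integer(format(t, "%j", tz = "UTC"))
  as.integer(ceiling(doy / 7))
}
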