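# Synthetic stimulus generators: rate-coded pattern maps, Poisson spike
# trains, and the solar-cell transduction of optical spikes into voltage
# pulses.  These emulate the optical front end of the hardware: each pixel of
# a pattern is a homogeneous Poisson source whose events are converted to
# ~1 V open-circuit-voltage pulses by a miniature solar cell.

new_rate_map <- function(grid, label) {
  size <- nrow(grid)
  out <- tibble::tibble(
    row  = rep(seq_len(size), each = size),
    col  = rep(seq_len(size), times = size),
    rate = as.vector(t(grid))
  )
  structure(out, class = c("rate_map", class(out)), size = size, label = label)
}

#' Coerce a rate map to a numeric matrix
#'
#' @param map A `rate_map` as produced by [make_orientation_pattern()],
#'   [make_cross_pattern()] or [make_noise_pattern()].
#' @return A `size x size` numeric matrix of Poisson rates (Hz).
#' @export
rate_map_matrix <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  size <- attr(map, "size")
  m <- matrix(0, size, size)
  m[cbind(map$row, map$col)] <- map$rate
  m
}

# Flatten a rate map to the row-major vector used by the network readout
# (1-based pixel ids match the row-major synapse numbering in reports).
rate_map_vector <- function(map) {
  as.vector(t(rate_map_matrix(map)))
}

#' Oriented-bar rate pattern
#'
#' Builds a square grid of Poisson rates in which a one-pixel-wide bar through
#' the centre fires at `high_rate` and every other pixel at `low_rate`.  Bar
#' geometry: 0 degrees is the centre row, 90 the centre column, 45 the main
#' diagonal and 135 the anti-diagonal.
#'
#' @param size Odd grid dimension (3 or 9 for the tasks shipped here).
#' @param angle Bar orientation in degrees; one of 0, 45, 90, 135.
#' @param high_rate,low_rate Pixel rates in Hz, `high_rate > low_rate >= 0`
#'   (equal rates give a degenerate uniform map).
#' @return A `rate_map` tibble with columns `row`, `col`, `rate`.
#' @examples
#' make_orientation_pattern(9, 90, 30, 14)
#' @export
make_orientation_pattern <- function(size, angle, high_rate = 30, low_rate = 14) {
  check_number(size, "size", lower = 3)
  if (size %% 2 == 0) abort("`size` must be odd so the bar passes through the centre.")
  if (!angle %in% c(0, 45, 90, 135)) {
    abort(sprintf("Unsupported `angle` %s: must be one of 0, 45, 90, 135 degrees.", angle))
  }
  check_number(low_rate, "low_rate", lower = 0)
  check_number(high_rate, "high_rate", lower = low_rate)
  grid <- matrix(low_rate, size, size)
  mid <- (size + 1L) / 2L
  idx <- switch(as.character(angle),
    "0"   = cbind(mid, seq_len(size)),
    "90"  = cbind(seq_len(size), mid),
    "45"  = cbind(seq_len(size), seq_len(size)),
    "135" = cbind(seq_len(size), rev(seq_len(size)))
  )
  grid[idx] <- high_rate
  new_rate_map(grid, label = paste0("bar", angle))
}

#' Diagonal-cross ('X') rate pattern
#'
#' 3x3 pattern used for crossbar learning: the corners and centre (pixels
#' 1, 3, 5, 7, 9 in row-major, 1-based numbering) fire at `high_rate`, the
#' edge pixels (2, 4, 6, 8) at `low_rate`.
#'
#' @inheritParams make_orientation_pattern
#' @return A `rate_map` tibble.
#' @export
make_cross_pattern <- function(high_rate = 30, low_rate = 14) {
  check_number(low_rate, "low_rate", lower = 0)
  check_number(high_rate, "high_rate", lower = 0)
  grid <- matrix(low_rate, 3, 3)
  grid[cbind(c(1, 1, 2, 3, 3), c(1, 3, 2, 1, 3))] <- high_rate
  new_rate_map(grid, label = "X")
}

#' Structureless noise rate pattern
#'
#' Deprivation input: every pixel draws an independent rate uniformly on
#' `[lo, hi]` Hz.  Used as the image seen by a deprived eye.
#'
#' @inheritParams make_orientation_pattern
#' @param lo,hi Rate bounds in Hz, `0 <= lo <= hi`.
#' @param seed Optional integer seed for reproducibility.
#' @return A `rate_map` tibble.
#' @export
make_noise_pattern <- function(size, lo = 4, hi = 6, seed = NULL) {
  check_number(size, "size", lower = 1)
  check_number(lo, "lo", lower = 0)
  if (lo > hi) abort(sprintf("`lo` (%g) must not exceed `hi` (%g).", lo, hi))
  grid <- with_seed(seed, matrix(stats::runif(size^2, lo, hi), size, size))
  new_rate_map(grid, label = "noise")
}

#' Homogeneous Poisson spike train
#'
#' Samples event times by exponential inter-arrival times at constant rate.
#'
#' @param rate Event rate in Hz (>= 0).
#' @param duration Window length in ms (> 0).
#' @param seed Optional integer seed.
#' @return A `spike_train` tibble with column `time_ms` (strictly increasing,
#'   all in `[0, duration]`); the window length is kept in attribute
#'   `duration`.
#' @export
poisson_train <- function(rate, duration, seed = NULL) {
  check_number(rate, "rate", lower = 0)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  times <- if (rate == 0) numeric(0) else with_seed(seed, {
    # draw in blocks of the expected count (+ margin) until past `duration`
    rate_ms <- rate / 1000
    n_block <- max(16L, ceiling(rate_ms * duration * 1.25))
    acc <- cumsum(stats::rexp(n_block, rate_ms))
    while (acc[length(acc)] < duration) {
      acc <- c(acc, acc[length(acc)] + cumsum(stats::rexp(n_block, rate_ms)))
    }
    acc[acc <= duration]
  })
  out <- tibble::tibble(time_ms = times)
  structure(out, class = c("spike_train", class(out)), duration = duration)
}

# Default open-circuit-voltage map: logarithmic in irradiance, anchored at
# 1.0 V for 100 mW/cm^2 (solar-cell Voc grows ~ log of light intensity).
voc_map <- function(irradiance) {
  stopifnot(all(irradiance >= 0))
  log1p(irradiance) / log1p(100)
}

#' Solar-cell transduction of optical spikes to voltage pulses
#'
#' One voltage pulse per optical spike, amplitude given by a monotone map of
#' irradiance (1.0 V at 100 mW/cm^2 by default).  Spikes closer than one pulse
#' width are merged into a single pulse; zero-amplitude pulses are dropped.
#'
#' @param train A `spike_train`.
#' @param irradiance Optical irradiance in mW/cm^2 (>= 0).
#' @param pulse_width Electrical pulse width in ms (> 0).
#' @param amplitude_map Monotone function irradiance -> volts; the default is
#'   logarithmic with `amplitude_map(100) == 1`.
#' @return A `pulse_train` tibble with columns `time_ms`, `amplitude_v`,
#'   `width_ms`; consecutive pulses are separated by at least `width_ms`.
#' @export
phototransduce <- function(train, irradiance = 100, pulse_width = 5,
                           amplitude_map = voc_map) {
  stopifnot(inherits(train, "spike_train"))
  check_number(irradiance, "irradiance", lower = 0)
  check_number(pulse_width, "pulse_width", lower = 0, strict_lower = TRUE)
  amp <- amplitude_map(irradiance)
  times <- train$time_ms
  if (length(times) == 0 || amp <= 0) {
    out <- tibble::tibble(time_ms = numeric(0), amplitude_v = numeric(0),
                          width_ms = numeric(0))
  } else {
    keep <- c(TRUE, diff(times) >= pulse_width)
    # greedy merge: re-scan because dropping a pulse can expose a new conflict
    while (!all(keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= pulse_width)
    }
    out <- tibble::tibble(time_ms = times, amplitude_v = amp,
                          width_ms = pulse_width)
  }
  structure(out, class = c("pulse_train", class(out)),
            duration = attr(train, "duration"))
}

#' Regular (clock-driven) voltage pulse train
#'
#' Convenience constructor for fixed-frequency protocols (potentiation trains,
#' frequency-history experiments): `n` pulses at a given frequency.
#'
#' @param n Number of pulses.
#' @param freq_hz Pulse frequency (Hz); the inter-pulse interval is
#'   `1000 / freq_hz` ms.
#' @param amplitude_v Pulse amplitude (V); negative values depress.
#' @param width_ms Pulse width (ms).
#' @param t0 Time of the first pulse (ms).
#' @return A `pulse_train` tibble.
#' @export
pulse_train <- function(n, freq_hz, amplitude_v = 0.5, width_ms = 5, t0 = 0) {
  check_number(n, "n", lower = 1)
  check_number(freq_hz, "freq_hz", lower = 0, strict_lower = TRUE)
  interval <- 1000 / freq_hz
  if (interval < width_ms) {
    abort(sprintf("Pulses overlap: interval %.3g ms < width %.3g ms.", interval, width_ms))
  }
  out <- tibble::tibble(
    time_ms = t0 + (seq_len(n) - 1) * interval,
    amplitude_v = amplitude_v,
    width_ms = width_ms
  )
  structure(out, class = c("pulse_train", class(out)),
            duration = t0 + n * interval)
}
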