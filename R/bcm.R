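# Rate-based BCM learning engine.
#
# The weight dynamics are the rate-based expectation of the minimal all-to-all
# triplet rule: dG/dt = (-A2- tau- rho_y - A3- tau- tau_x rho_x rho_y
# + A2+ tau+ rho_y + A3+ tau+ tau_y rho_y^2) * rho_x, with A3- = 0 and the
# pair amplitudes rescaled by <rho_y^2> / rho_0^2.  That rescaling yields the
# sliding modification threshold
# theta = <rho_y^2> (A2- tau- - A2+ tau+) / (rho_0^2 A3+ tau+ tau_y),
# and the dynamics reduce to dG/dt = phi(rho_y, theta) * rho_x with
# phi = rho_y * A3+ tau+ tau_y * (rho_y - theta): negative below threshold,
# zero at 0 and at threshold, positive above.  <rho_y^2> is tracked as an
# exponential moving average.  Time constants are stored in ms and converted
# to seconds inside the rate equations, so rates are plain Hz.

MS <- 1e-3  # ms -> s

#' BCM parameter set
#'
#' @param triplet A `triplet_params` set; `A3_minus` must be 0 for the
#'   minimal rule (enforced here) and amplitudes set the learning rate.  The
#'   default scales the shipped STDP kernel down to per-epoch weight changes
#'   of order 1e-4 of the weight range.
#' @param rho0 Reference rate constant (Hz, > 0); together with the kernel
#'   constants it fixes the fixed-point firing scale
#'   `rho0^2 * A3+ tau+ tau_y / (A2- tau- - A2+ tau+)`.
#' @param tau_avg Averaging time constant of the postsynaptic second moment
#'   (ms); default 10 s of simulated time.
#' @param w_min,w_max Weight bounds (hard clipping); defaults are the device
#'   conductance window expressed as dimensionless weights
#'   (conductance / 4.5 mS reference).
#' @return A list of class `bcm_params`.
#' @export
bcm_params <- function(triplet = scale_triplet(triplet_params(A3_minus = 0,
                                                              tau_supp = 0),
                                               2e-6),
                       rho0 = 15, tau_avg = 1e4,
                       w_min = 50 / 4500, w_max = 350 / 4500) {
  stopifnot(inherits(triplet, "triplet_params"))
  if (triplet$A3_minus != 0) {
    abort("The minimal BCM triplet rule requires `A3_minus` = 0.")
  }
  check_threshold_positivity(triplet, action = abort)
  check_number(rho0, "rho0", lower = 0, strict_lower = TRUE)
  check_number(tau_avg, "tau_avg", lower = 0, strict_lower = TRUE)
  check_number(w_min, "w_min")
  check_number(w_max, "w_max", lower = w_min, strict_lower = TRUE)
  structure(list(triplet = triplet, rho0 = rho0, tau_avg = tau_avg,
                 w_min = w_min, w_max = w_max),
            class = "bcm_params")
}

#' Rescale the amplitudes of a triplet kernel
#'
#' Multiplies the four kernel amplitudes by `s`, leaving time constants (and
#' hence the BCM threshold, which depends only on amplitude ratios)
#' unchanged.  Used to convert the unit-scale STDP kernel into a rate-based
#' learning rate, or between weight units.
#'
#' @param params A `triplet_params` set.
#' @param s Positive scale factor.
#' @return A `triplet_params` set.
#' @export
scale_triplet <- function(params, s) {
  check_number(s, "s", lower = 0, strict_lower = TRUE)
  for (nm in c("A2_plus", "A2_minus", "A3_plus", "A3_minus")) {
    params[[nm]] <- params[[nm]] * s
  }
  params
}

#' BCM modification function
#'
#' Reduced form `phi(rho_y, theta) = rho_y * A3+ tau+ tau_y * (rho_y -
#' theta)`: zero at `rho_y = 0` and at `rho_y = theta`, negative between,
#' positive above.
#'
#' @param rho_y Postsynaptic rate(s), Hz (>= 0).
#' @param theta Modification threshold, Hz.
#' @param params A `bcm_params` set.
#' @return Modification factor (weight units per second per Hz of
#'   presynaptic drive).
#' @export
phi <- function(rho_y, theta, params = bcm_params()) {
  if (any(rho_y < 0)) abort("`rho_y` must be >= 0.")
  tr <- params$triplet
  out <- rho_y * (tr$A3_plus * tr$tau_plus * MS * tr$tau_y * MS) * (rho_y - theta)
  out + 0  # normalize IEEE negative zero at the exact roots
}

#' Sliding modification threshold
#'
#' `theta = avg * (A2- tau- - A2+ tau+) / (rho0^2 * A3+ tau+ tau_y)`;
#' proportional to the running second moment of the postsynaptic rate.
#'
#' @param avg_rho_y_sq Running mean of `rho_y^2` (Hz^2, >= 0).
#' @param params A `bcm_params` set.
#' @return Threshold in Hz (>= 0 by the parameter invariant).
#' @export
slide_theta <- function(avg_rho_y_sq, params = bcm_params()) {
  if (any(avg_rho_y_sq < 0)) abort("`avg_rho_y_sq` must be >= 0.")
  tr <- params$triplet
  num <- tr$A2_minus * tr$tau_minus * MS - tr$A2_plus * tr$tau_plus * MS
  den <- params$rho0^2 * tr$A3_plus * tr$tau_plus * MS * tr$tau_y * MS
  theta <- avg_rho_y_sq * num / den
  if (any(theta < 0)) {
    abort("Negative threshold: parameters violate A2- tau- > A2+ tau+.")
  }
  theta
}

#' Rate-based BCM weight derivative
#'
#' The expanded quadratic form with `A3- = 0` and the pair amplitudes scaled
#' by `avg_rho_y_sq / rho0^2`.  Equal to `phi(rho_y, slide_theta(avg)) *
#' rho_x`.
#'
#' @param rho_x Presynaptic rate(s), Hz (vectorized over synapses).
#' @param rho_y Postsynaptic rate, Hz.
#' @param avg_rho_y_sq Running mean of `rho_y^2` (Hz^2).
#' @param params A `bcm_params` set.
#' @return dG/dt in weight units per second, same length as `rho_x`.
#' @export
bcm_dGdt <- function(rho_x, rho_y, avg_rho_y_sq, params = bcm_params()) {
  if (any(rho_x < 0) || any(rho_y < 0)) abort("Rates must be >= 0.")
  tr <- params$triplet
  scale <- avg_rho_y_sq / params$rho0^2
  (-tr$A2_minus * scale * tr$tau_minus * MS * rho_y -
     tr$A3_minus * tr$tau_minus * MS * tr$tau_x * MS * rho_x * rho_y +
     tr$A2_plus * scale * tr$tau_plus * MS * rho_y +
     tr$A3_plus * tr$tau_plus * MS * tr$tau_y * MS * rho_y^2) * rho_x
}

#' BCM state
#'
#' @param weights Initial weight vector.
#' @param params A `bcm_params` set.
#' @param probe_rho_y Postsynaptic rate of one probe presentation used to
#'   initialize the second-moment average (avoids the `theta = 0` pathology
#'   at start); defaults to the mid-scale rate `rho0`.
#' @return A list of class `bcm_state` with fields `w`, `theta`,
#'   `avg_rho_y_sq` and the parameters.
#' @export
bcm_state <- function(weights, params = bcm_params(), probe_rho_y = NULL) {
  stopifnot(is.numeric(weights), length(weights) >= 1)
  if (any(weights < params$w_min - 1e-12) || any(weights > params$w_max + 1e-12)) {
    abort("Initial weights outside [w_min, w_max].")
  }
  if (is.null(probe_rho_y)) probe_rho_y <- params$rho0
  avg <- probe_rho_y^2
  structure(list(w = weights, avg_rho_y_sq = avg,
                 theta = slide_theta(avg, params), params = params),
            class = "bcm_state")
}

#' Update the running postsynaptic second moment
#'
#' Exponential moving average of `rho_y^2` with time constant `tau_avg`;
#' recomputes the threshold.
#'
#' @param state A `bcm_state`.
#' @param rho_y Observed postsynaptic rate (Hz).
#' @param dt Elapsed time (ms, > 0).
#' @return The updated `bcm_state`.
#' @export
update_average <- function(state, rho_y, dt) {
  stopifnot(inherits(state, "bcm_state"))
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  alpha <- 1 - exp(-dt / state$params$tau_avg)
  state$avg_rho_y_sq <- state$avg_rho_y_sq + alpha * (rho_y^2 - state$avg_rho_y_sq)
  state$theta <- slide_theta(state$avg_rho_y_sq, state$params)
  state
}

#' One Euler step of the BCM dynamics
#'
#' Computes `rho_y = sum(w * rho_x)` (or uses a supplied realized rate),
#' updates every weight by `bcm_dGdt * dt` with hard clipping to the bounds,
#' then slides the threshold via [update_average()].
#'
#' @param state A `bcm_state`.
#' @param rho_x Presynaptic rate vector (Hz), same length as the weights.
#' @param dt Step length (ms).
#' @param rho_y Optional realized postsynaptic rate overriding the linear
#'   readout (used when rates are Poisson-realized upstream).
#' @return The updated `bcm_state` with the `rho_y` used stored in field
#'   `last_rho_y`.
#' @export
bcm_step <- function(state, rho_x, dt, rho_y = NULL) {
  stopifnot(inherits(state, "bcm_state"))
  if (length(rho_x) != length(state$w)) {
    abort(sprintf("Dimension mismatch: %d rates for %d weights.",
                  length(rho_x), length(state$w)))
  }
  p <- state$params
  if (is.null(rho_y)) rho_y <- sum(state$w * rho_x)
  dG <- bcm_dGdt(rho_x, rho_y, state$avg_rho_y_sq, p) * dt * MS
  state$w <- pmin(pmax(state$w + dG, p$w_min), p$w_max)
  state <- update_average(state, rho_y, dt)
  state$last_rho_y <- rho_y
  state
}
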