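# Phenomenological model of the perovskite memristive synapse.
#
# The device is modelled with two conductance components and one activity
# trace: G_long is the persistent (written) part of the conductance, G_short a
# short-term component that relaxes back within ~200 ms, and u a dimensionless
# activity trace standing in for the slow redistribution of halogenic
# vacancies (the second-order, Ca2+-like variable).  Each voltage pulse
# increments u, writes a conductance increment scaled by the remaining window
# (soft bounds), and the read current (EPSC) is V * G.  Integration is
# event-driven: decays between pulses are applied in closed form, so the
# model has no step-size tolerance.

#' Device parameter set
#'
#' @param G_min,G_max Conductance bounds (uS); `G_min < G_max`.
#' @param tau_u Decay time constant of the activity trace u (ms).
#' @param kappa_u Per-pulse increment of u (dimensionless).
#' @param eta_p,eta_d Potentiation/depression efficacy (uS per V*ms at zero
#'   facilitation, before the window factor).
#' @param beta Facilitation gain: a pulse arriving at activity u writes
#'   `(1 + beta * u)` times the baseline increment.
#' @param tau_short Relaxation time constant of the short-term conductance
#'   component (ms); 60 ms puts the EPSC back to ~4% of its peak in 200 ms.
#' @param retain_frac Fraction of each per-pulse conductance increment written
#'   to the persistent component (0..1); the rest decays with `tau_short`.
#' @param decay_frac Fraction of the above-floor conductance that behaves as
#'   relaxable when a stored state `G0` is probed; used by the pair-STDP decay
#'   offset (see [pair_stdp_dw()]).
#' @return A list of class `device_params`.
#' @export
device_params <- function(G_min = 50, G_max = 350, tau_u = 12, kappa_u = 1,
                          eta_p = 6.4787, eta_d = 6.4787, beta = 0.009275,
                          tau_short = 60, retain_frac = 0.2,
                          decay_frac = 0.1) {
  check_number(G_min, "G_min")
  check_number(G_max, "G_max", lower = G_min, strict_lower = TRUE)
  check_number(tau_u, "tau_u", lower = 0, strict_lower = TRUE)
  check_number(tau_short, "tau_short", lower = 0, strict_lower = TRUE)
  check_number(kappa_u, "kappa_u", lower = 0)
  check_number(eta_p, "eta_p", lower = 0)
  check_number(eta_d, "eta_d", lower = 0)
  check_number(beta, "beta", lower = 0)
  check_number(retain_frac, "retain_frac", lower = 0, upper = 1)
  check_number(decay_frac, "decay_frac", lower = 0, upper = 1)
  structure(list(G_min = G_min, G_max = G_max, tau_u = tau_u,
                 kappa_u = kappa_u, eta_p = eta_p, eta_d = eta_d, beta = beta,
                 tau_short = tau_short, retain_frac = retain_frac,
                 decay_frac = decay_frac),
            class = "device_params")
}

#' Device state
#'
#' @param params A `device_params` set.
#' @param G0 Initial total conductance (uS); defaults to `G_min`.  The excess
#'   above `G_min` is stored in the persistent component.
#' @return A list of class `device_state` with fields `G_long`, `G_short`,
#'   `u`, `t` (ms) and the parameter set.
#' @export
device_state <- function(params = device_params(), G0 = NULL) {
  stopifnot(inherits(params, "device_params"))
  if (is.null(G0)) G0 <- params$G_min
  check_number(G0, "G0", lower = params$G_min, upper = params$G_max)
  structure(list(G_long = G0, G_short = 0, u = 0, t = 0, params = params),
            class = "device_state")
}

#' Total device conductance
#' @param state A `device_state`.
#' @return Conductance `G_long + G_short` in uS.
#' @export
conductance <- function(state) state$G_long + state$G_short

#' Double-exponential paired-pulse facilitation model
#'
#' `PPF(dt) = c1 * exp(-dt / tau1) + c2 * exp(-dt / tau2)`: the sum of a rapid
#' and a slow relaxation phase, in percent.
#'
#' @param dt Inter-pulse interval(s), ms (>= 0).
#' @param c1,c2 Initial magnitudes of the rapid and slow phases (%).
#' @param tau1,tau2 Relaxation time constants (ms, > 0).
#' @return PPF value(s) in percent.
#' @export
ppf_model <- function(dt, c1, c2, tau1, tau2) {
  if (any(dt < 0)) abort("`dt` must be >= 0.")
  check_number(tau1, "tau1", lower = 0, strict_lower = TRUE)
  check_number(tau2, "tau2", lower = 0, strict_lower = TRUE)
  c1 * exp(-dt / tau1) + c2 * exp(-dt / tau2)
}

#' Fit the double-exponential PPF decay
#'
#' Nonlinear least squares fit of [ppf_model()] to measured PPF ratios,
#' returning phases ordered so that `tau1 <= tau2`.  A fit is flagged
#' degenerate when one phase carries (almost) no amplitude or the two time
#' constants coincide -- i.e. the data are effectively single-exponential and
#' the split into rapid/slow phases is not identifiable.
#'
#' @param intervals Inter-pulse intervals (ms); at least 5, spanning both
#'   decay regimes.
#' @param ppf_values Measured PPF ratios (%), same length.
#' @return An object of class `ppf_fit`: a list with `c1`, `c2`, `tau1`,
#'   `tau2`, `residual` (residual standard error), `degenerate` flag and the
#'   underlying `nls` fit.  Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
fit_ppf <- function(intervals, ppf_values) {
  stopifnot(is.numeric(intervals), is.numeric(ppf_values),
            length(intervals) == length(ppf_values))
  if (length(intervals) < 5) abort("Need at least 5 (interval, PPF) points.")
  if (any(intervals < 0)) abort("Intervals must be >= 0.")
  df <- data.frame(dt = intervals, ppf = ppf_values)
  df <- df[order(df$dt), ]
  # data-driven starts: slow phase from the tail, fast phase from the head
  tail_n <- max(3L, ceiling(nrow(df) / 3))
  tail_df <- df[df$ppf > 0, ][seq(to = sum(df$ppf > 0), length.out = tail_n), ]
  tau2_0 <- tryCatch({
    cf <- stats::coef(stats::lm(log(ppf) ~ dt, data = tail_df))
    max(min(-1 / cf[2], max(df$dt) * 10), max(df$dt) / 20)
  }, error = function(e) max(df$dt) / 3)
  tau1_0 <- max(min(df$dt[df$dt > 0]), tau2_0 / 50)
  amp0 <- max(df$ppf) / 2
  # facilitation noise is multiplicative (instrument noise scales with the
  # response), so fit relative errors: weights 1 / y^2
  w <- 1 / pmax(abs(df$ppf), 1e-8 * max(abs(df$ppf)))^2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ppf ~ c1 * exp(-dt / tau1) + c2 * exp(-dt / tau2), data = df,
      start = list(c1 = amp0, c2 = amp0, tau1 = tau1_0, tau2 = tau2_0),
      lower = c(0, 0, 1e-6, 1e-6), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # the two-phase model is not identifiable on these data (typically a
    # single-exponential decay); fall back to one phase and flag it
    single <- tryCatch(
      minpack.lm::nlsLM(ppf ~ c2 * exp(-dt / tau2), data = df,
                        start = list(c2 = max(df$ppf), tau2 = tau2_0),
                        lower = c(0, 1e-6), weights = w),
      error = function(e) abort(paste0("PPF fit failed: ", conditionMessage(e)))
    )
    cf <- stats::coef(single)
    warn("PPF fit is degenerate: data are consistent with a single exponential phase.")
    return(structure(list(c1 = 0, c2 = unname(cf[["c2"]]),
                          tau1 = unname(cf[["tau2"]]), tau2 = unname(cf[["tau2"]]),
                          residual = summary(single)$sigma, degenerate = TRUE,
                          swapped = FALSE, single = TRUE, fit = single,
                          data = tibble::as_tibble(df)),
                     class = "ppf_fit"))
  }
  cf <- stats::coef(fit)
  swapped <- cf[["tau1"]] > cf[["tau2"]]
  if (swapped) {
    cf <- cf[c("c2", "c1", "tau2", "tau1")]
    names(cf) <- c("c1", "c2", "tau1", "tau2")
  }
  amp_tot <- cf[["c1"]] + cf[["c2"]]
  degenerate <- amp_tot <= 0 ||
    min(cf[["c1"]], cf[["c2"]]) / amp_tot < 0.02 ||
    cf[["tau2"]] / cf[["tau1"]] < 1.5
  if (degenerate) {
    warn("PPF fit is degenerate: data are consistent with a single exponential phase.")
  }
  structure(list(c1 = unname(cf[["c1"]]), c2 = unname(cf[["c2"]]),
                 tau1 = unname(cf[["tau1"]]), tau2 = unname(cf[["tau2"]]),
                 residual = summary(fit)$sigma, degenerate = degenerate,
                 swapped = swapped, single = FALSE, fit = fit,
                 data = tibble::as_tibble(df)),
            class = "ppf_fit")
}

# window factor: remaining head-room for potentiation, remaining floor-room
# for depression; linear in G (soft bounds).
conductance_window <- function(G, amplitude, params) {
  span <- params$G_max - params$G_min
  if (amplitude >= 0) (params$G_max - G) / span else (G - params$G_min) / span
}

#' Apply one voltage pulse to the device
#'
#' Increments the activity trace, writes a window-limited conductance
#' increment (split between the persistent and short-term components) and
#' returns the read current.
#'
#' @param state A `device_state`.
#' @param amplitude Pulse amplitude (V); negative pulses depress.
#' @param width Pulse width (ms).
#' @return A list with the updated `state` and `epsc`, the peak EPSC in uA
#'   (`V * G` after the update).
#' @export
apply_pulse <- function(state, amplitude = 0.5, width = 5) {
  stopifnot(inherits(state, "device_state"))
  check_number(width, "width", lower = 0, strict_lower = TRUE)
  p <- state$params
  state$u <- state$u + p$kappa_u
  if (amplitude != 0) {
    G <- conductance(state)
    eta <- if (amplitude > 0) p$eta_p else p$eta_d
    dG <- sign(amplitude) * eta * abs(amplitude) * width *
      (1 + p$beta * state$u) * conductance_window(G, amplitude, p)
    # never write past the bounds even if the window factor under-corrects
    dG <- max(min(dG, p$G_max - G), p$G_min - G)
    state$G_long <- state$G_long + p$retain_frac * dG
    state$G_short <- state$G_short + (1 - p$retain_frac) * dG
  }
  list(state = state, epsc = abs(amplitude) * conductance(state))
}

#' Relax the device for a time interval
#'
#' Closed-form exponential decay of the activity trace and the short-term
#' conductance component; the persistent component is unchanged.
#'
#' @param state A `device_state`.
#' @param dt Elapsed time (ms, >= 0).
#' @return The relaxed `device_state`.
#' @export
relax <- function(state, dt) {
  stopifnot(inherits(state, "device_state"))
  check_number(dt, "dt", lower = 0)
  p <- state$params
  state$u <- state$u * exp(-dt / p$tau_u)
  state$G_short <- state$G_short * exp(-dt / p$tau_short)
  state$t <- state$t + dt
  state
}

#' Run a voltage pulse train through the device
#'
#' Alternates [relax()] and [apply_pulse()] over an ordered pulse train.
#'
#' @param state A `device_state`.
#' @param train A `pulse_train` (columns `time_ms`, `amplitude_v`,
#'   `width_ms`), strictly ordered in time with non-overlapping pulses.
#' @return A list with `trace` (tibble: `time_ms`, `G_uS`, `EPSC_uA` sampled
#'   after each pulse) and the final `state`.
#' @export
run_train <- function(state, train) {
  stopifnot(inherits(state, "device_state"), is.data.frame(train))
  n <- nrow(train)
  if (n > 1) {
    gaps <- diff(train$time_ms)
    if (any(gaps <= 0)) abort("Pulses must be strictly ordered in time.")
    if (any(gaps < train$width_ms[-n])) abort("Pulses overlap: gap smaller than pulse width.")
  }
  G <- numeric(n); epsc <- numeric(n)
  for (i in seq_len(n)) {
    state <- relax(state, train$time_ms[i] - state$t)
    res <- apply_pulse(state, train$amplitude_v[i], train$width_ms[i])
    state <- res$state
    G[i] <- conductance(state)
    epsc[i] <- res$epsc
  }
  list(trace = tibble::tibble(time_ms = train$time_ms, G_uS = G, EPSC_uA = epsc),
       state = state)
}

#' Paired-pulse facilitation ratio from a two-pulse simulation
#'
#' Runs two identical pulses separated by `dt` and returns
#' `(A2 - A1) / A1 * 100` where `A1`, `A2` are the two EPSC peaks.
#'
#' @param params A `device_params` set.
#' @param dt Inter-pulse interval (ms).
#' @param amplitude,width Pulse shape (V, ms).
#' @param G0 Initial conductance; defaults to `G_min`.
#' @return PPF ratio in percent.
#' @export
ppf_ratio <- function(params, dt, amplitude = 0.5, width = 5, G0 = NULL) {
  st <- device_state(params, G0)
  r1 <- apply_pulse(st, amplitude, width)
  st <- relax(r1$state, dt)
  r2 <- apply_pulse(st, amplitude, width)
  (r2$epsc - r1$epsc) / r1$epsc * 100
}

#' Potentiation/depression conductance staircase
#'
#' `n` potentiating pulses followed by `n` depressing pulses, recording the
#' conductance after each pulse.
#'
#' @param params A `device_params` set.
#' @param n Pulses per branch (>= 2).
#' @param amplitude,width Pulse shape; the depression branch uses
#'   `-amplitude`.
#' @param interval Inter-pulse interval (ms).
#' @param G0 Starting conductance; defaults to `G_min`.
#' @return A tibble with columns `pulse` (1..2n), `phase`
#'   ("potentiation"/"depression") and `G_uS`.
#' @export
potentiation_depression_curve <- function(params, n = 100, amplitude = 0.5,
                                          width = 5, interval = 10, G0 = NULL) {
  check_number(n, "n", lower = 2)
  st <- device_state(params, G0)
  up <- run_train(st, pulse_train(n, 1000 / interval, amplitude, width))
  down <- run_train(up$state,
                    pulse_train(n, 1000 / interval, -amplitude, width,
                                t0 = up$state$t + interval))
  tibble::tibble(
    pulse = seq_len(2 * n),
    phase = rep(c("potentiation", "depression"), each = n),
    G_uS = c(up$trace$G_uS, down$trace$G_uS)
  )
}

# Saturating-exponential weight-update model used for the nonlinearity index:
# G(P) = G_start + B * (1 - exp(-P / A)),  B = (G_end - G_start) / (1 - exp(-Pmax / A)),
# with NL defined as Pmax / A (0 = linear, larger = more curved).  P counts
# applied pulses starting at 0, so the first recorded point is G_start.
nl_model <- function(P, P_max, G_start, G_end, NL) {
  if (NL <= 0) return(G_start + (G_end - G_start) * P / P_max)
  A <- P_max / NL
  B <- (G_end - G_start) / (1 - exp(-P_max / A))
  G_start + B * (1 - exp(-P / A))
}

#' Synthesize a potentiation/depression curve at a given nonlinearity
#'
#' @param n Number of pulses.
#' @param G_start,G_end Conductance end points (uS); `G_end < G_start` gives a
#'   depression curve.
#' @param NL Nonlinearity index (`P_max / A` of the saturating-exponential
#'   model; 0 is linear).
#' @return Numeric vector of `n` conductances.
#' @export
nl_curve <- function(n, G_start, G_end, NL) {
  check_number(n, "n", lower = 2)
  check_number(NL, "NL", lower = 0)
  nl_model(seq_len(n) - 1, n - 1, G_start, G_end, NL)
}

#' Extract the nonlinearity index of a conductance staircase
#'
#' Fits the one-parameter saturating-exponential model (see [nl_curve()]) to a
#' monotone conductance sequence by least squares over the curvature
#' parameter, and returns the nonlinearity index `NL = P_max / A`.  A linear
#' staircase gives NL ~ 0; larger values mean a more curved (front-loaded)
#' update.
#'
#' @param curve Monotone numeric vector of conductances (>= 10 points), one
#'   per pulse; either branch direction is accepted.
#' @return The NL index (single number) with the fitted model stored in
#'   attribute `fit`.
#' @export
extract_nonlinearity <- function(curve) {
  stopifnot(is.numeric(curve))
  if (length(curve) < 10) abort("Need a curve with at least 10 points.")
  d <- diff(curve)
  if (!(all(d >= 0) || all(d <= 0))) {
    abort("`curve` must be monotone (a single potentiation or depression branch).")
  }
  n <- length(curve)
  P <- seq_len(n) - 1
  sse <- function(log_NL) {
    sum((curve - nl_model(P, n - 1, curve[1], curve[n], exp(log_NL)))^2)
  }
  opt <- stats::optimize(sse, interval = log(c(1e-3, 1e3)))
  NL <- exp(opt$minimum)
  # linear data push the optimum to the lower search edge; report ~0
  if (opt$minimum < log(1e-3) + 1e-6) NL <- 0
  structure(NL, fit = list(G_start = curve[1], G_end = curve[n], n = n,
                           sse = opt$objective))
}

#' Shipped device calibration
#'
#' Returns the default device parameter set with the write efficacy `eta_p`
#' and facilitation gain `beta` fitted (nonlinear least squares) so that a
#' 10-pulse 0.5 V / 5 ms train read from the default initial state yields a
#' peak EPSC of 76.3 uA at 5 ms inter-pulse interval and 62.1 uA at 15 ms.
#' The fit is deterministic and takes well under a second; all other
#' constants keep their documented defaults.
#'
#' @param anchors Target peak EPSCs (uA) for the two intervals.
#' @param intervals Inter-pulse intervals (ms) of the anchor protocols.
#' @param n_pulses Train length of the anchor protocol.
#' @param base Parameter set supplying the non-fitted constants.
#' @return A calibrated `device_params` set.
#' @export
calibrate_defaults <- function(anchors = c(76.3, 62.1), intervals = c(5, 15),
                               n_pulses = 10, base = device_params()) {
  stopifnot(length(anchors) == length(intervals), length(anchors) >= 2)
  peak <- function(eta_p, beta, interval) {
    p <- base
    p$eta_p <- eta_p; p$beta <- beta
    res <- run_train(device_state(p), pulse_train(n_pulses, 1000 / interval))
    max(res$trace$EPSC_uA)
  }
  resid <- function(par) {
    eta_p <- exp(par[1]); beta <- exp(par[2])
    vapply(seq_along(anchors),
           function(i) peak(eta_p, beta, intervals[i]) - anchors[i],
           numeric(1))
  }
  fit <- minpack.lm::nls.lm(par = log(c(base$eta_p, base$beta)), fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  out <- base
  out$eta_p <- exp(fit$par[1])
  out$eta_d <- out$eta_p
  out$beta <- exp(fit$par[2])
  if (sum(resid(fit$par)^2) > 1e-4) {
    warn("Device calibration did not reach the anchor EPSCs exactly.")
  }
  out
}
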