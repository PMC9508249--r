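# Pair- and triplet spike-timing-dependent plasticity.
#
# The triplet rule follows the standard detector formulation: two presynaptic
# traces (fast: tau_plus, slow: tau_x) and two postsynaptic traces (fast:
# tau_minus, slow: tau_y).  Each postsynaptic spike potentiates by the fast
# presynaptic trace times (A2+ + A3+ * slow postsynaptic trace); each
# presynaptic spike depresses by the fast postsynaptic trace times
# (A2- + A3- * slow presynaptic trace).  Accumulation is all-to-all (traces
# persist across spikes).  "First-spike-dominating" suppression scales each
# spike's efficacy by 1 - exp(-dt_same_side / tau_supp).

#' Triplet-STDP kernel parameters
#'
#' Defaults use the canonical triplet-model time constants (16.8 / 33.7 /
#' 101 / 125 ms); amplitudes are in relative weight units per event and are
#' chosen so that `A2_minus * tau_minus > A2_plus * tau_plus`, the condition
#' for a positive BCM modification threshold.
#'
#' @param A2_plus,A2_minus Pair potentiation/depression amplitudes (>= 0).
#' @param A3_plus,A3_minus Triplet potentiation/depression amplitudes (>= 0).
#' @param tau_plus,tau_minus Fast pre-/postsynaptic trace constants (ms).
#' @param tau_x,tau_y Slow pre-/postsynaptic trace constants (ms).
#' @param tau_supp Same-side suppression recovery constant (ms); 0 disables
#'   suppression.
#' @return A list of class `triplet_params`.
#' @export
triplet_params <- function(A2_plus = 0.8, A2_minus = 1.0, A3_plus = 2.0,
                           A3_minus = 0.1, tau_plus = 16.8, tau_minus = 33.7,
                           tau_x = 101, tau_y = 125, tau_supp = 20) {
  for (nm in c("A2_plus", "A2_minus", "A3_plus", "A3_minus")) {
    check_number(get(nm), nm, lower = 0)
  }
  for (nm in c("tau_plus", "tau_minus", "tau_x", "tau_y")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  check_number(tau_supp, "tau_supp", lower = 0)
  out <- structure(list(A2_plus = A2_plus, A2_minus = A2_minus,
                        A3_plus = A3_plus, A3_minus = A3_minus,
                        tau_plus = tau_plus, tau_minus = tau_minus,
                        tau_x = tau_x, tau_y = tau_y, tau_supp = tau_supp),
                   class = "triplet_params")
  check_threshold_positivity(out)
  out
}

check_threshold_positivity <- function(params, action = warn) {
  if (params$A2_minus * params$tau_minus <= params$A2_plus * params$tau_plus) {
    action(paste0(
      "A2_minus * tau_minus (", params$A2_minus * params$tau_minus,
      ") must exceed A2_plus * tau_plus (", params$A2_plus * params$tau_plus,
      ") for a positive BCM threshold."))
    return(FALSE)
  }
  TRUE
}

#' State-dependent decay offset for pair STDP
#'
#' The conductance stored in a history state `G0` partially relaxes while the
#' pair protocol plays out; the offset is the relaxable fraction of the
#' above-floor conductance lost over the pulse interval.  Monotone increasing
#' in both `G0` and `|dt|`.
#'
#' @param params A `device_params` set (supplies `G_min`, `tau_short` and
#'   `decay_frac`).
#' @return A function `f(G0, abs_dt)` returning the offset in uS.
#' @export
device_decay_offset <- function(params = device_params()) {
  force(params)
  function(G0, abs_dt) {
    params$decay_frac * pmax(G0 - params$G_min, 0) *
      (1 - exp(-abs_dt / params$tau_short))
  }
}

#' History-dependent pair-STDP weight change
#'
#' Exponential pair kernel minus a state-dependent decay offset: at high
#' initial conductance the relaxation outweighs the timing-driven gain, so
#' the sign of the change can flip even in the conventional potentiation
#' region.
#'
#' @param dt Spike lag `t_post - t_pre` in ms; must be nonzero (simultaneous
#'   spikes are undefined).
#' @param G0 Initial conductance state (uS).
#' @param params A `triplet_params` set; only the pair amplitudes and fast
#'   time constants are used.  Amplitudes here are interpreted in uS.
#' @param decay Offset function `f(G0, abs_dt)` as produced by
#'   [device_decay_offset()]; replaceable.
#' @param kernel_scale Multiplier mapping the kernel amplitudes to uS
#'   (default 30, i.e. `A2_plus = 1` peaks at 30 uS).
#' @return Weight change(s) in uS.
#' @export
pair_stdp_dw <- function(dt, G0, params = triplet_params(),
                         decay = device_decay_offset(), kernel_scale = 30) {
  if (any(dt == 0)) abort("`dt` = 0 is undefined for pair STDP.")
  kern <- ifelse(dt > 0,
                 kernel_scale * params$A2_plus * exp(-dt / params$tau_plus),
                 -kernel_scale * params$A2_minus * exp(dt / params$tau_minus))
  kern - decay(G0, abs(dt))
}

#' Run the triplet-STDP rule over a pre/post spike-train pair
#'
#' All-to-all accumulation with per-side first-spike suppression (see the
#' module description).  The event loop runs in compiled code.
#'
#' @param pre_train,post_train `spike_train` objects (or tibbles with a
#'   `time_ms` column), each strictly time-ordered; simultaneous pre and post
#'   spikes are rejected.
#' @param params A `triplet_params` set.
#' @param w_init Initial weight (default 0).
#' @return A tibble of per-event updates (`time_ms`, `side`, `dw`, `w`) with
#'   the net change in attribute `dw_total`.
#' @export
triplet_apply <- function(pre_train, post_train, params = triplet_params(),
                          w_init = 0) {
  pre <- if (is.data.frame(pre_train)) pre_train$time_ms else as.numeric(pre_train)
  post <- if (is.data.frame(post_train)) post_train$time_ms else as.numeric(post_train)
  if (is.unsorted(pre, strictly = TRUE) || is.unsorted(post, strictly = TRUE)) {
    abort("Spike trains must be strictly increasing in time.")
  }
  res <- triplet_core(pre, post,
                      params$A2_plus, params$A2_minus, params$A3_plus,
                      params$A3_minus, params$tau_plus, params$tau_minus,
                      params$tau_x, params$tau_y, params$tau_supp, w_init)
  out <- tibble::tibble(
    time_ms = res$time_ms,
    side = ifelse(res$side == 0, "pre", "post"),
    dw = res$dw, w = res$w
  )
  structure(out, dw_total = res$w_total)
}

# Build the 3-spike trains realizing a (dt1, dt2) point of the quadrant map.
# Q2 (dt1 < 0 < dt2): post-pre-post; Q4 (dt2 < 0 < dt1): pre-post-pre;
# Q1 (both > 0): pre-pre-post (both pre before the post);
# Q3 (both < 0): post-post-pre (both post before the pre).
triplet_sequence <- function(dt1, dt2) {
  if (dt1 == 0 || dt2 == 0) abort("Quadrant grids must exclude 0.")
  if (dt1 < 0 && dt2 > 0) {
    list(ordering = "post-pre-post", pre = 0, post = sort(c(dt1, dt2)), quadrant = "II")
  } else if (dt1 > 0 && dt2 < 0) {
    list(ordering = "pre-post-pre", pre = sort(c(-dt1, -dt2)), post = 0, quadrant = "IV")
  } else if (dt1 > 0 && dt2 > 0) {
    if (dt1 == dt2) abort("Coincident presynaptic spikes are undefined.")
    list(ordering = "pre-pre-post", pre = sort(c(-dt1, -dt2)), post = 0, quadrant = "I")
  } else {
    if (dt1 == dt2) abort("Coincident postsynaptic spikes are undefined.")
    list(ordering = "post-post-pre", pre = 0, post = sort(c(dt1, dt2)), quadrant = "III")
  }
}

#' Triplet-STDP quadrant map
#'
#' Evaluates the triplet rule on the three-spike sequence corresponding to
#' every (dt1, dt2) grid point: 'post-pre-post' in quadrant II, 'pre-post-pre'
#' in IV, and the pre-always-first / post-always-first sequences in I and III.
#' Lags are signed as `t_post - t_pre` against the middle spike.
#'
#' @param dt1_grid,dt2_grid Lag grids in ms; zeros are excluded.
#' @param params A `triplet_params` set.
#' @return A tibble with `dt1`, `dt2`, `quadrant`, `ordering` and the signed
#'   weight change `dG`; supports [ggplot2::autoplot()].
#' @export
quadrant_map <- function(dt1_grid, dt2_grid, params = triplet_params()) {
  if (any(dt1_grid == 0) || any(dt2_grid == 0)) abort("Quadrant grids must exclude 0.")
  grid <- tidyr::expand_grid(dt1 = dt1_grid, dt2 = dt2_grid)
  grid <- grid[grid$dt1 != grid$dt2 | sign(grid$dt1) != sign(grid$dt2), ]
  res <- purrr::pmap(grid, function(dt1, dt2) {
    sq <- triplet_sequence(dt1, dt2)
    tr <- triplet_apply(tibble::tibble(time_ms = sq$pre),
                        tibble::tibble(time_ms = sq$post), params)
    tibble::tibble(dt1 = dt1, dt2 = dt2, quadrant = sq$quadrant,
                   ordering = sq$ordering, dG = attr(tr, "dw_total"))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("quadrant_map", class(out))
  out
}

#' Fit triplet-STDP kernel parameters to (sequence, dG) observations
#'
#' Least-squares fit of the four amplitudes and four time constants (the
#' suppression constant is held fixed) to observed weight changes of
#' three-spike sequences, via Levenberg-Marquardt on log-scaled parameters.
#'
#' @param observations A data frame with columns `dt1`, `dt2` (ms, signed as
#'   in [quadrant_map()]) and `dG`; needs >= 8 rows covering both quadrants II
#'   and IV, otherwise the fit is underdetermined and rejected.
#' @param start Starting parameter set.
#' @param tau_supp Suppression constant used during fitting.
#' @return A `triplet_fit` object: fitted `params`, `residual` (RMS),
#'   `fitted`/`observed` values and a `constraint_ok` flag
#'   (`A2_minus * tau_minus > A2_plus * tau_plus`); warns when the fitted
#'   parameters violate the threshold-positivity constraint.  Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_triplet_params <- function(observations, start = triplet_params(),
                               tau_supp = start$tau_supp) {
  stopifnot(is.data.frame(observations),
            all(c("dt1", "dt2", "dG") %in% names(observations)))
  if (nrow(observations) < 8) {
    abort("Underdetermined: need at least 8 observations to fit 8 kernel parameters.")
  }
  quad <- mapply(function(a, b) triplet_sequence(a, b)$quadrant,
                 observations$dt1, observations$dt2)
  if (!all(c("II", "IV") %in% quad)) {
    abort(paste0("Underdetermined: observations must span quadrants II and IV ",
                 "(got ", paste(sort(unique(quad)), collapse = ", "), "); ",
                 "potentiation and depression kernels are not separately ",
                 "identifiable otherwise."))
  }
  seqs <- purrr::map2(observations$dt1, observations$dt2, triplet_sequence)
  predict_dG <- function(p) {
    vapply(seqs, function(sq) {
      attr(triplet_apply(tibble::tibble(time_ms = sq$pre),
                         tibble::tibble(time_ms = sq$post), p), "dw_total")
    }, numeric(1))
  }
  par_names <- c("A2_plus", "A2_minus", "A3_plus", "A3_minus",
                 "tau_plus", "tau_minus", "tau_x", "tau_y")
  unpack <- function(par) {
    vals <- exp(par)
    p <- start
    p[par_names] <- as.list(vals)
    p$tau_supp <- tau_supp
    p
  }
  resid <- function(par) observations$dG - predict_dG(unpack(par))
  start_vec <- log(pmax(unlist(start[par_names]), 1e-6))
  fit <- minpack.lm::nls.lm(par = start_vec, fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  params <- unpack(fit$par)
  constraint_ok <- check_threshold_positivity(params)
  fitted_vals <- predict_dG(params)
  structure(list(params = params,
                 residual = sqrt(mean((observations$dG - fitted_vals)^2)),
                 fitted = fitted_vals, observed = observations$dG,
                 constraint_ok = constraint_ok, convergence = fit$info),
            class = "triplet_fit")
}
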