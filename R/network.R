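# Network-level experiments.
#
# (i) Crossbar pattern learning: a 3x3 array of optically driven synapses and
# one output cell.  Each 200 ms epoch, per-pixel Poisson spikes are read out
# as a summed current I = w0 * sum(G_i * f_i) (f_i = realized spike count
# relative to the count a reference-rate input would produce), fed back as a
# firing rate rho_y = g * I, and the BCM rule updates the conductances.  In
# expectation this is exactly the reduced form rho_y = sum(w_i * rho_x_i)
# with w_i = g * w0 * G_i / (1000 * rho_norm), which is also how the 9x9
# simulation is run.
#
# (ii) Rearing: two 9x9 input layers (left/right eye) converge on one
# cortical cell, rho_y = Gl . rho_xl + Gr . rho_xr.  Per epoch one of four
# oriented bars is drawn; under monocular deprivation the deprived eye sees
# uniform 4-6 Hz noise instead, under binocular deprivation both eyes do.

#' Linear readout rate of a weight vector
#'
#' `mode = "reduced"`: `rho_y = sum(w * rho_x)` summed over eyes, with
#' dimensionless weights.  `mode = "hardware"`: a one-shot crossbar read,
#' `I = w0 * sum(G)` in mA (conductances in uS) and `rho_y = g * I`; the rate
#' maps are ignored apart from a dimension check.
#'
#' @param weights Weight vector (dimensionless), or conductances in uS for
#'   the hardware mode; for two eyes give a list of two vectors.
#' @param ratemaps A `rate_map` or list of rate maps (one per eye).
#' @param mode Readout path.
#' @param w0 Read amplitude (V).
#' @param g Current-to-rate gain (Hz/mA).
#' @return Postsynaptic rate in Hz.
#' @export
readout_rate <- function(weights, ratemaps, mode = c("reduced", "hardware"),
                         w0 = 0.5, g = 50) {
  mode <- match.arg(mode)
  if (inherits(ratemaps, "rate_map")) ratemaps <- list(ratemaps)
  if (!is.list(weights)) weights <- list(weights)
  if (length(weights) != length(ratemaps)) {
    abort("Need one weight vector per rate map (per eye).")
  }
  rates <- lapply(ratemaps, rate_map_vector)
  for (i in seq_along(weights)) {
    if (length(weights[[i]]) != length(rates[[i]])) {
      abort(sprintf("Dimension mismatch in eye %d: %d weights vs %d pixels.",
                    i, length(weights[[i]]), length(rates[[i]])))
    }
  }
  if (mode == "reduced") {
    sum(vapply(seq_along(weights),
               function(i) sum(weights[[i]] * rates[[i]]), numeric(1)))
  } else {
    I_mA <- w0 * sum(unlist(weights)) * 1e-3  # uS * V -> uA; /1000 -> mA
    g * I_mA
  }
}

# Dimensionless weight of one device conductance under the hardware loop
# constants: w = g * w0 * G[uS -> mS] / rho_norm.
hardware_weight <- function(G_uS, w0, g, rho_norm) {
  g * w0 * G_uS * 1e-3 / rho_norm
}

#' Modification threshold stored in a device history state
#'
#' Bridges the device history state to the BCM threshold: a synapse held at
#' conductance `G0` and probed through the hardware loop fires at
#' `rho_y = g * w0 * G0`, so the stored second moment is `rho_y^2` and the
#' threshold follows from [slide_theta()].  Strictly increasing in `G0`.
#'
#' @param G0 History conductance state(s) in uS.
#' @param params A `bcm_params` set.
#' @param w0,g Hardware loop constants (V, Hz/mA).
#' @return Threshold(s) in Hz.
#' @export
history_theta <- function(G0, params = bcm_params(), w0 = 0.5, g = 50) {
  stopifnot(all(G0 >= 0))
  rho_y <- g * w0 * G0 * 1e-3
  slide_theta(rho_y^2, params)
}

#' Crossbar learning configuration
#'
#' @param pattern Input `rate_map` (default the 30/14 Hz 'X').
#' @param w0 Read amplitude (V).
#' @param g Current-to-rate gain (Hz/mA).
#' @param window Integration window = epoch duration (ms).
#' @param epochs Number of presentation epochs.
#' @param seed Root seed.
#' @param device A `device_params` set supplying the conductance bounds.
#' @param rho0 BCM reference rate (Hz).
#' @param tau_avg Second-moment averaging constant (ms).
#' @param learn_scale Amplitude scale applied to the unit triplet kernel to
#'   obtain per-second conductance changes in uS.
#' @param init_frac Initial weights are drawn uniformly from the bottom
#'   `init_frac` of the conductance window.
#' @param rho_norm Reference input rate (Hz) defining the hardware
#'   count-to-current normalization.
#' @param record_every Trace recording stride (epochs).
#' @return A list of class `crossbar_config`.
#' @export
crossbar_config <- function(pattern = make_cross_pattern(), w0 = 0.5, g = 50,
                            window = 200, epochs = 2000, seed = 1,
                            device = device_params(), rho0 = 15,
                            tau_avg = 1e4, learn_scale = 0.024,
                            init_frac = 0.1, rho_norm = 30,
                            record_every = 10) {
  stopifnot(inherits(pattern, "rate_map"), inherits(device, "device_params"))
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  check_number(g, "g", lower = 0, strict_lower = TRUE)
  check_number(epochs, "epochs", lower = 1)
  check_number(init_frac, "init_frac", lower = 0, upper = 1)
  bcm <- bcm_params(
    triplet = scale_triplet(triplet_params(A3_minus = 0, tau_supp = 0),
                            learn_scale),
    rho0 = rho0, tau_avg = tau_avg,
    w_min = device$G_min, w_max = device$G_max
  )
  structure(list(pattern = pattern, w0 = w0, g = g, window = window,
                 epochs = as.integer(epochs), seed = seed, device = device,
                 bcm = bcm, learn_scale = learn_scale, init_frac = init_frac,
                 rho_norm = rho_norm,
                 record_every = as.integer(record_every)),
            class = "crossbar_config")
}

#' Run the crossbar pattern-learning experiment
#'
#' @param config A `crossbar_config`.
#' @return A `crossbar_fit` object: `final` (tibble `synapse`, `rate`,
#'   `G_uS`), `weight_trace`, `rate_trace` (per-epoch `rho_y`, `theta`) and
#'   the config.  Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
run_crossbar_learning <- function(config = crossbar_config()) {
  stopifnot(inherits(config, "crossbar_config"))
  rho_x <- rate_map_vector(config$pattern)
  n_syn <- length(rho_x)
  dev <- config$device
  dur_s <- config$window * 1e-3
  count_norm <- config$rho_norm * dur_s

  with_seed(config$seed, {
    G <- stats::runif(n_syn, dev$G_min,
                      dev$G_min + config$init_frac * (dev$G_max - dev$G_min))
    rho_y0 <- config$g * config$w0 * 1e-3 * sum(G * rho_x / config$rho_norm)
    state <- bcm_state(G, config$bcm, probe_rho_y = rho_y0)

    n_rec <- length(seq(1L, config$epochs, by = config$record_every))
    w_rec <- matrix(NA_real_, n_rec, n_syn)
    rec_epochs <- integer(n_rec)
    rho_trace <- numeric(config$epochs)
    theta_trace <- numeric(config$epochs)
    r <- 0L
    for (e in seq_len(config$epochs)) {
      counts <- stats::rpois(n_syn, rho_x * dur_s)
      rho_x_hat <- counts / dur_s
      I_mA <- config$w0 * sum(state$w * 1e-3 * counts / count_norm)
      rho_y <- config$g * I_mA
      state <- bcm_step(state, rho_x_hat, config$window, rho_y = rho_y)
      rho_trace[e] <- rho_y
      theta_trace[e] <- state$theta
      if ((e - 1L) %% config$record_every == 0L) {
        r <- r + 1L
        w_rec[r, ] <- state$w
        rec_epochs[r] <- e
      }
    }

    weight_trace <- tibble::tibble(
      epoch = rep(rec_epochs, each = n_syn),
      synapse = rep(seq_len(n_syn), times = n_rec),
      G_uS = as.vector(t(w_rec))
    )
    structure(list(
      final = tibble::tibble(synapse = seq_len(n_syn), rate = rho_x,
                             G_uS = state$w),
      weight_trace = weight_trace,
      rate_trace = tibble::tibble(epoch = seq_len(config$epochs),
                                  rho_y = rho_trace, theta = theta_trace),
      state = state, config = config
    ), class = "crossbar_fit")
  })
}

#' Rearing protocol for the binocular orientation-selectivity experiment
#'
#' @param condition One of `"normal"`, `"monocular_deprivation"` (alias
#'   `"md"`), `"binocular_deprivation"` (alias `"bd"`).
#' @param size Grid dimension of each eye (odd).
#' @param orientations Bar angles presented (degrees).
#' @param high_rate,low_rate Bar pixel rates (Hz).
#' @param noise_range Deprivation noise rate bounds (Hz).
#' @param epochs Number of presentation epochs.
#' @param epoch_duration Presentation length (ms).
#' @param seed Root seed.
#' @param deprived_eye Eye receiving noise under monocular deprivation.
#' @param noise_mode `"redraw"` (new noise image every epoch, default) or
#'   `"frozen"` (one noise image per eye for the whole run).
#' @param G_ref Reference conductance (uS) converting the device window into
#'   dimensionless weights.
#' @param device Device parameter set supplying the conductance window.
#' @param rho0,tau_avg,learn_scale BCM constants (see [bcm_params()]).
#' @param init_frac Initial weights drawn uniformly from the bottom
#'   `init_frac` of the weight range.
#' @param record_every Weight-trace recording stride (epochs).
#' @return A list of class `rearing_protocol`.
#' @export
rearing_protocol <- function(condition = c("normal", "monocular_deprivation",
                                           "binocular_deprivation", "md", "bd"),
                             size = 9, orientations = c(0, 45, 90, 135),
                             high_rate = 30, low_rate = 14,
                             noise_range = c(4, 6), epochs = 18000,
                             epoch_duration = 200, seed = 1,
                             deprived_eye = c("right", "left"),
                             noise_mode = c("redraw", "frozen"),
                             G_ref = 4500, device = device_params(),
                             rho0 = 15, tau_avg = 1e4, learn_scale = 1e-5,
                             init_frac = 0.1, record_every = 25) {
  condition <- match.arg(condition)
  condition <- switch(condition, md = "monocular_deprivation",
                      bd = "binocular_deprivation", condition)
  deprived_eye <- match.arg(deprived_eye)
  noise_mode <- match.arg(noise_mode)
  check_number(epochs, "epochs", lower = 1)
  check_number(epoch_duration, "epoch_duration", lower = 0, strict_lower = TRUE)
  check_number(G_ref, "G_ref", lower = 0, strict_lower = TRUE)
  stopifnot(length(noise_range) == 2, noise_range[1] >= 0,
            noise_range[1] <= noise_range[2])
  bcm <- bcm_params(
    triplet = scale_triplet(triplet_params(A3_minus = 0, tau_supp = 0),
                            learn_scale),
    rho0 = rho0, tau_avg = tau_avg,
    w_min = device$G_min / G_ref, w_max = device$G_max / G_ref
  )
  structure(list(condition = condition, size = size,
                 orientations = orientations, high_rate = high_rate,
                 low_rate = low_rate, noise_range = noise_range,
                 epochs = as.integer(epochs),
                 epoch_duration = epoch_duration, seed = seed,
                 deprived_eye = deprived_eye, noise_mode = noise_mode,
                 G_ref = G_ref, bcm = bcm, learn_scale = learn_scale,
                 init_frac = init_frac,
                 record_every = as.integer(record_every)),
            class = "rearing_protocol")
}

#' Run a rearing experiment
#'
#' Per epoch, one orientation label is drawn uniformly; each eye receives
#' either that bar or a noise image according to the rearing condition, pixel
#' spike counts are Poisson-realized, the cortical cell fires at
#' `rho_y = Gl . rho_xl + Gr . rho_xr`, and both eyes' weights plus the
#' sliding threshold are updated by the BCM rule.
#'
#' @param protocol A `rearing_protocol`.
#' @return A `tuning_result` object: per-eye final `weight_maps`,
#'   `weight_trace`, `rate_trace` (per-epoch presented `orientation`,
#'   realized `rho_y` and `theta`) and the protocol.  Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
run_rearing <- function(protocol = rearing_protocol()) {
  stopifnot(inherits(protocol, "rearing_protocol"))
  pr <- protocol
  n_pix <- pr$size^2
  bars <- vapply(pr$orientations, function(a) {
    rate_map_vector(make_orientation_pattern(pr$size, a, pr$high_rate,
                                             pr$low_rate))
  }, numeric(n_pix))  # n_pix x n_orient
  dur_s <- pr$epoch_duration * 1e-3
  n_ori <- length(pr$orientations)
  left_deprived <- pr$condition == "binocular_deprivation" ||
    (pr$condition == "monocular_deprivation" && pr$deprived_eye == "left")
  right_deprived <- pr$condition == "binocular_deprivation" ||
    (pr$condition == "monocular_deprivation" && pr$deprived_eye == "right")

  with_seed(pr$seed, {
    p <- pr$bcm
    w <- stats::runif(2 * n_pix, p$w_min,
                      p$w_min + pr$init_frac * (p$w_max - p$w_min))
    # one probe presentation (mean over orientations) initializes theta
    mean_bar <- rowMeans(bars)
    probe <- sum(w[1:n_pix] * mean_bar) + sum(w[n_pix + 1:n_pix] * mean_bar)
    state <- bcm_state(w, p, probe_rho_y = probe)

    frozen_l <- stats::runif(n_pix, pr$noise_range[1], pr$noise_range[2])
    frozen_r <- stats::runif(n_pix, pr$noise_range[1], pr$noise_range[2])
    draw_noise <- function(frozen) {
      if (pr$noise_mode == "frozen") frozen
      else stats::runif(n_pix, pr$noise_range[1], pr$noise_range[2])
    }

    labels <- sample(pr$orientations, pr$epochs, replace = TRUE)
    rec_epochs <- seq(1L, pr$epochs, by = pr$record_every)
    w_rec <- matrix(NA_real_, length(rec_epochs), 2 * n_pix)
    rho_trace <- numeric(pr$epochs)
    theta_trace <- numeric(pr$epochs)
    r <- 0L
    for (e in seq_len(pr$epochs)) {
      o <- match(labels[e], pr$orientations)
      rate_l <- if (left_deprived) draw_noise(frozen_l) else bars[, o]
      rate_r <- if (right_deprived) draw_noise(frozen_r) else bars[, o]
      rho_x <- c(stats::rpois(n_pix, rate_l * dur_s),
                 stats::rpois(n_pix, rate_r * dur_s)) / dur_s
      state <- bcm_step(state, rho_x, pr$epoch_duration)
      rho_trace[e] <- state$last_rho_y
      theta_trace[e] <- state$theta
      if ((e - 1L) %% pr$record_every == 0L) {
        r <- r + 1L
        w_rec[r, ] <- state$w
      }
    }

    grid_rc <- expand.grid(col = seq_len(pr$size), row = seq_len(pr$size))
    weight_maps <- tibble::tibble(
      eye = rep(c("left", "right"), each = n_pix),
      pixel = rep(seq_len(n_pix), 2),
      row = rep(grid_rc$row, 2), col = rep(grid_rc$col, 2),
      weight = state$w
    )
    weight_trace <- tibble::tibble(
      epoch = rep(rec_epochs, each = 2 * n_pix),
      eye = rep(rep(c("left", "right"), each = n_pix), length(rec_epochs)),
      pixel = rep(rep(seq_len(n_pix), 2), length(rec_epochs)),
      weight = as.vector(t(w_rec))
    )
    structure(list(
      weight_maps = weight_maps,
      weight_trace = weight_trace,
      rate_trace = tibble::tibble(epoch = seq_len(pr$epochs),
                                  orientation = labels, rho_y = rho_trace,
                                  theta = theta_trace),
      state = state, protocol = pr
    ), class = "tuning_result")
  })
}

# Steady-state summary over the final fraction of epochs: mean realized rate
# per presented orientation plus the mean threshold.
steady_state_rates <- function(result, frac = 0.1) {
  rt <- result$rate_trace
  cut <- stats::quantile(rt$epoch, 1 - frac)
  ss <- rt[rt$epoch >= cut, ]
  rates <- tapply(ss$rho_y, ss$orientation, mean)
  list(rates = rates, theta = mean(ss$theta))
}

#' Winner orientation of a rearing run
#'
#' The winner is the orientation with the highest steady-state response
#' (mean realized rate over the final `frac` of epochs), provided it exceeds
#' the steady-state threshold and beats the runner-up by more than `tie_tol`
#' (relative).  Otherwise `NA` is returned, with the reason ("subthreshold"
#' or "tie") in attribute `reason`.
#'
#' @param result A `tuning_result`.
#' @param frac Final fraction of epochs treated as steady state.
#' @param tie_tol Relative margin below which the top two orientations are an
#'   unresolved tie.
#' @return Winning orientation in degrees, or `NA`.
#' @export
winner_orientation <- function(result, frac = 0.1, tie_tol = 0.05) {
  stopifnot(inherits(result, "tuning_result"))
  ss <- steady_state_rates(result, frac)
  rates <- sort(ss$rates, decreasing = TRUE)
  top <- rates[1]
  if (top <= ss$theta) {
    return(structure(NA_real_, reason = "subthreshold"))
  }
  if (length(rates) > 1 && (top - rates[2]) / top <= tie_tol) {
    return(structure(NA_real_, reason = "tie"))
  }
  as.numeric(names(rates)[1])
}

#' Selectivity summary of a rearing run
#'
#' @param result A `tuning_result`.
#' @param frac Steady-state fraction of epochs.
#' @return A one-row tibble: `winner` (degrees or NA), `winner_rate` (Hz),
#'   `theta` (Hz), `margin` (`winner_rate - theta`), and `eye_matching`, the
#'   cosine similarity between the two eyes' final weight maps.
#' @export
selectivity_metrics <- function(result, frac = 0.1) {
  stopifnot(inherits(result, "tuning_result"))
  ss <- steady_state_rates(result, frac)
  winner <- winner_orientation(result, frac)
  top <- max(ss$rates)
  wl <- result$weight_maps$weight[result$weight_maps$eye == "left"]
  wr <- result$weight_maps$weight[result$weight_maps$eye == "right"]
  cosine <- sum(wl * wr) / sqrt(sum(wl^2) * sum(wr^2))
  tibble::tibble(winner = as.numeric(winner), winner_rate = top,
                 theta = ss$theta, margin = top - ss$theta,
                 eye_matching = cosine)
}
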