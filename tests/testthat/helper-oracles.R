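# Shared fixtures and independent oracles.

# Rate-based expectation of the all-to-all triplet rule for independent
# Poisson pre/post trains (kernel units, rates in Hz, taus in ms).  This is
# the analytic stationary mean of dw/dt, used as the oracle against the
# event-driven simulation.
expected_dwdt <- function(rho_x, rho_y, p) {
  ms <- 1e-3
  (-p$A2_minus * p$tau_minus * ms * rho_y -
     p$A3_minus * p$tau_minus * ms * p$tau_x * ms * rho_x * rho_y +
     p$A2_plus * p$tau_plus * ms * rho_y +
     p$A3_plus * p$tau_plus * ms * p$tau_y * ms * rho_y^2) * rho_x
}

# Monte-Carlo mean and standard error of dw/dt (per second) over independent
# chunks of Poisson pre/post trains.
mc_dwdt <- function(rho_x, rho_y, p, chunk_ms = 4e4, n_chunks = 50) {
  dw <- vapply(seq_len(n_chunks), function(i) {
    pre <- poisson_train(rho_x, chunk_ms)
    post <- poisson_train(rho_y, chunk_ms)
    attr(triplet_apply(pre, post, p), "dw_total") / (chunk_ms * 1e-3)
  }, numeric(1))
  list(mean = mean(dw), se = stats::sd(dw) / sqrt(n_chunks))
}

# Random triplet parameter set satisfying the threshold-positivity
# constraint (A2- tau- > A2+ tau+), for property tests.
random_valid_triplet <- function() {
  tau_plus <- stats::runif(1, 5, 40)
  tau_minus <- stats::runif(1, 5, 60)
  A2_minus <- stats::runif(1, 0.5, 3)
  # keep A2+ tau+ strictly below A2- tau-
  A2_plus <- stats::runif(1, 0, 0.9 * A2_minus * tau_minus / tau_plus)
  triplet_params(A2_plus = A2_plus, A2_minus = A2_minus,
                 A3_plus = stats::runif(1, 0.5, 4), A3_minus = 0,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 tau_x = stats::runif(1, 50, 200),
                 tau_y = stats::runif(1, 50, 200), tau_supp = 0)
}

# Four-train frequency-history protocol (100/10/1/10 Hz); returns the net
# conductance change of each train.
four_train_dG <- function(params, n = c(50, 8, 3, 10),
                          freqs = c(100, 10, 1, 10)) {
  st <- device_state(params)
  t0 <- 0
  out <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    tr <- pulse_train(n[i], freqs[i], t0 = t0)
    G0 <- conductance(st)
    res <- run_train(st, tr)
    st <- res$state
    out[i] <- conductance(st) - G0
    t0 <- st$t + 1000 / freqs[i]
  }
  out
}

# Minimal hand-built tuning_result for winner-rule unit tests.
fake_tuning_result <- function(rates_by_ori, theta, epochs = 1000) {
  oris <- rep(c(0, 45, 90, 135), length.out = epochs)
  rt <- tibble::tibble(
    epoch = seq_len(epochs),
    orientation = oris,
    rho_y = rates_by_ori[as.character(oris)],
    theta = theta
  )
  pr <- rearing_protocol("normal", epochs = epochs)
  wm <- tibble::tibble(eye = rep(c("left", "right"), each = 81),
                       pixel = rep(1:81, 2), row = 1, col = 1,
                       weight = rep(stats::runif(81, 0.01, 0.08), 2))
  structure(list(weight_maps = wm, weight_trace = NULL, rate_trace = rt,
                 state = NULL, protocol = pr),
            class = "tuning_result")
}
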