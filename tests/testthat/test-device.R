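test_that("ppf_model evaluates the double exponential", {
  expect_equal(ppf_model(0, 30, 20, 1, 10), 50)
  expect_lt(ppf_model(1e6, 50, 50, 0.28, 10.86), 1e-12)
  # direct arithmetic: 50*exp(-10.86/0.28) + 50*exp(-1)
  expect_equal(ppf_model(10.86, 50, 50, 0.28, 10.86),
               50 * exp(-10.86 / 0.28) + 50 * exp(-1))
  expect_equal(ppf_model(10.86, 50, 50, 0.28, 10.86), 18.394, tolerance = 1e-4)
  expect_error(ppf_model(1, 50, 50, -1, 10), "tau1")
})

test_that("fit_ppf recovers noiseless parameters and flags degeneracy", {
  dts <- c(exp(seq(log(0.1), log(0.8), length.out = 8)),
           exp(seq(log(1.1), log(50), length.out = 12)))
  y <- ppf_model(dts, 60, 40, 0.3, 12)
  f <- fit_ppf(dts, y)
  expect_equal(f$c1, 60, tolerance = 1e-4)
  expect_equal(f$c2, 40, tolerance = 1e-4)
  expect_equal(f$tau1, 0.3, tolerance = 1e-4)
  expect_equal(f$tau2, 12, tolerance = 1e-4)
  expect_false(f$degenerate)
  expect_lte(f$tau1, f$tau2)

  # pure single exponential: the rapid/slow split is unidentifiable
  y1 <- ppf_model(dts, 0, 80, 0.3, 12)
  expect_warning(f1 <- fit_ppf(dts, y1), "degenerate")
  expect_true(f1$degenerate)

  expect_error(fit_ppf(1:3, 1:3), "at least 5")
})

test_that("fit_ppf tidiers expose estimates and fit quality", {
  dts <- exp(seq(log(0.1), log(50), length.out = 20))
  set.seed(2)
  y <- ppf_model(dts, 50, 50, 0.28, 10.86) * (1 + rnorm(20, 0, 0.02))
  f <- fit_ppf(dts, y)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("c1", "c2", "tau1", "tau2"))
  gl <- glance(f)
  expect_equal(gl$nobs, 20)
  expect_false(gl$degenerate)
})

test_that("pulses move conductance inside the window and report EPSC", {
  p <- device_params()
  st <- device_state(p, G0 = 200)

  # 0 V pulse: only the activity trace moves
  r0 <- apply_pulse(st, 0, 5)
  expect_equal(conductance(r0$state), 200)
  expect_equal(r0$state$u, st$u + p$kappa_u)

  # potentiation from mid-range increases G, bounded by G_max
  r1 <- apply_pulse(st, 0.5, 5)
  expect_gt(conductance(r1$state), 200)
  expect_lte(conductance(r1$state), p$G_max)
  expect_equal(r1$epsc, 0.5 * conductance(r1$state))

  # saturated device: potentiating pulse is inert (window = 0)
  sat <- device_state(p, G0 = p$G_max)
  rs <- apply_pulse(sat, 0.5, 5)
  expect_equal(conductance(rs$state), p$G_max)

  # depression decreases G, bounded below
  rd <- apply_pulse(st, -0.5, 5)
  expect_lt(conductance(rd$state), 200)
  expect_gte(conductance(rd$state), p$G_min)
})

test_that("relax is an exponential-decay semigroup leaving G_long alone", {
  p <- device_params()
  st <- apply_pulse(device_state(p, G0 = 150), 0.5, 5)$state

  expect_equal(relax(st, 0)[c("G_long", "G_short", "u")],
               st[c("G_long", "G_short", "u")])

  a_then_b <- relax(relax(st, 37), 63)
  ab <- relax(st, 100)
  expect_equal(a_then_b$G_short, ab$G_short)
  expect_equal(a_then_b$u, ab$u)
  expect_equal(a_then_b$G_long, st$G_long)

  # EPSC transient is gone (~<5% of its peak) within 200 ms
  expect_lt(relax(st, 200)$G_short / st$G_short, 0.05)
})

test_that("conductance stays within [G_min, G_max] under random pulse trains", {
  p <- device_params()
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    gaps <- runif(n, 5, 60)
    tr <- tibble::tibble(time_ms = cumsum(gaps),
                         amplitude_v = sample(c(-1, 1), n, TRUE) * runif(n, 0.1, 1),
                         width_ms = 5)
    res <- run_train(device_state(p, G0 = runif(1, p$G_min, p$G_max)), tr)
    expect_true(all(res$trace$G_uS >= p$G_min - 1e-9))
    expect_true(all(res$trace$G_uS <= p$G_max + 1e-9))
  }
})

test_that("run_train rejects disordered or overlapping pulses", {
  st <- device_state()
  bad <- tibble::tibble(time_ms = c(10, 5), amplitude_v = 0.5, width_ms = 5)
  expect_error(run_train(st, bad), "ordered")
  over <- tibble::tibble(time_ms = c(0, 3), amplitude_v = 0.5, width_ms = 5)
  expect_error(run_train(st, over), "overlap")
})

test_that("frequency history gives the (+, -, ~0, +) four-train signature", {
  dG <- four_train_dG(device_params())
  tol <- 8  # uS; 'essentially unchanged' band for the 1 Hz train
  expect_gt(dG[1], tol)          # 100 Hz: excitation beats decay
  expect_lt(dG[2], -tol)         # 10 Hz from the elevated state: decay wins
  expect_lt(abs(dG[3]), tol)     # 1 Hz: balanced
  expect_gt(dG[4], tol)          # 10 Hz from the relaxed state: excitation wins
})

test_that("PPF ratio from two-pulse simulation decays with the interval", {
  p <- device_params()
  ivs <- c(2, 5, 10, 20, 50, 100, 200)
  pp <- vapply(ivs, function(d) ppf_ratio(p, d), numeric(1))
  expect_true(all(pp > 0))
  expect_true(all(diff(pp) < 0))
})

test_that("potentiation/depression staircase is monotone within bounds", {
  p <- device_params()
  cur <- potentiation_depression_curve(p, n = 100)
  up <- cur$G_uS[cur$phase == "potentiation"]
  down <- cur$G_uS[cur$phase == "depression"]
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(down) <= 0))
  expect_gte(min(cur$G_uS), p$G_min)
  expect_lte(max(cur$G_uS), p$G_max)
})

test_that("nonlinearity extraction round-trips and is ~0 for linear curves", {
  lin <- seq(50, 350, length.out = 100)
  expect_lt(as.numeric(extract_nonlinearity(lin)), 0.05)

  for (NL in c(1.5, 3.00, 3.98, 6)) {
    expect_equal(as.numeric(extract_nonlinearity(nl_curve(100, 50, 350, NL))),
                 NL, tolerance = 1e-3)
    # depression branch
    expect_equal(as.numeric(extract_nonlinearity(nl_curve(100, 350, 50, NL))),
                 NL, tolerance = 1e-3)
  }
  expect_error(extract_nonlinearity(c(1, 5, 3, 7, 2, 8, 4, 9, 1, 10)), "monotone")
  expect_error(extract_nonlinearity(1:5), "at least 10")
})

test_that("calibrated defaults hit the EPSC anchors and order by interval", {
  p <- calibrate_defaults()
  peaks <- vapply(c(5, 10, 15), function(iv) {
    max(run_train(device_state(p), pulse_train(10, 1000 / iv))$trace$EPSC_uA)
  }, numeric(1))
  expect_equal(peaks[1], 76.3, tolerance = 0.02)
  expect_equal(peaks[3], 62.1, tolerance = 0.02)
  expect_true(all(diff(peaks) < 0))  # peak EPSC decreasing in pulse interval
  # shipped defaults are the calibrated ones
  d <- device_params()
  expect_equal(p$eta_p, d$eta_p, tolerance = 0.01)
  expect_equal(p$beta, d$beta, tolerance = 0.05)
})
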