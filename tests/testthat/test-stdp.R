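test_that("triplet parameter invariants are enforced", {
  expect_error(triplet_params(tau_plus = -1), "tau_plus")
  expect_error(triplet_params(A2_plus = -0.1), "A2_plus")
  # threshold-positivity violation warns
  expect_warning(triplet_params(A2_plus = 2, A2_minus = 0.5), "positive BCM threshold")
})

test_that("pair STDP has the history-dependent sign structure", {
  p <- triplet_params()
  d <- device_decay_offset(device_params())

  # small positive lag, low history state: potentiation
  expect_gt(pair_stdp_dw(5, 100, p, d), 0)
  # negative lag: always depression
  expect_lt(pair_stdp_dw(-5, 100, p, d), 0)
  expect_lt(pair_stdp_dw(-40, 300, p, d), 0)
  # large positive lag at high G0: decay beats the kernel, sign flips
  expect_lt(pair_stdp_dw(50, 300, p, d), 0)
  # the sign flip happens at larger lags for lower G0 (weaker decay)
  lags <- seq(1, 80, by = 0.5)
  cross <- function(G0) lags[which(pair_stdp_dw(lags, G0, p, d) < 0)[1]]
  expect_gt(cross(100), cross(300))
  expect_error(pair_stdp_dw(0, 100, p, d), "undefined")
})

test_that("decay offset grows with history state and lag", {
  d <- device_decay_offset(device_params())
  expect_gt(d(300, 10), d(100, 10))
  expect_gt(d(200, 50), d(200, 5))
  expect_equal(d(50, 100), 0)  # floor state has nothing to relax
})

test_that("a single isolated pre-post pair follows the exponential kernel", {
  p <- triplet_params()
  for (lag in c(5, 15, 40)) {
    tr <- triplet_apply(tibble::tibble(time_ms = 0),
                        tibble::tibble(time_ms = lag), p)
    expect_equal(attr(tr, "dw_total"), p$A2_plus * exp(-lag / p$tau_plus))
  }
  # isolated post-pre pair: pure pair depression
  tr <- triplet_apply(tibble::tibble(time_ms = 10),
                      tibble::tibble(time_ms = 0), p)
  expect_equal(attr(tr, "dw_total"), -p$A2_minus * exp(-10 / p$tau_minus))
})

test_that("triplet rule reduces to pair STDP when triplet terms vanish", {
  # A3 = 0 and no suppression: any spike sequence accumulates pure pair terms
  p <- triplet_params(A3_plus = 0, A3_minus = 0, tau_supp = 0)
  pre <- c(0, 25, 60)
  post <- c(8, 40, 71)
  got <- attr(triplet_apply(tibble::tibble(time_ms = pre),
                            tibble::tibble(time_ms = post), p), "dw_total")
  # all-to-all pair sum computed directly
  want <- 0
  for (tp in pre) for (to in post) {
    dt <- to - tp
    want <- want + if (dt > 0) p$A2_plus * exp(-dt / p$tau_plus)
    else -p$A2_minus * exp(dt / p$tau_minus)
  }
  expect_equal(got, want)
})

test_that("empty or one-sided trains produce no weight change", {
  p <- triplet_params()
  none <- tibble::tibble(time_ms = numeric(0))
  pre <- tibble::tibble(time_ms = c(0, 10, 20))
  expect_equal(attr(triplet_apply(pre, none, p), "dw_total"), 0)
  expect_equal(attr(triplet_apply(none, pre, p), "dw_total"), 0)
})

test_that("simultaneous pre and post spikes are rejected", {
  p <- triplet_params()
  expect_error(triplet_apply(tibble::tibble(time_ms = c(0, 10)),
                             tibble::tibble(time_ms = c(10, 20)), p),
               "Simultaneous")
  expect_error(triplet_apply(tibble::tibble(time_ms = c(10, 5)),
                             tibble::tibble(time_ms = 1), p),
               "increasing")
})

test_that("Monte-Carlo triplet drift matches the analytic expectation", {
  p <- triplet_params(tau_supp = 0)
  set.seed(31)
  mc <- mc_dwdt(20, 25, p, chunk_ms = 4e4, n_chunks = 40)
  expect_lt(abs(mc$mean - expected_dwdt(20, 25, p)) / mc$se, 3)
})

test_that("quadrant map reproduces the four sign regions", {
  g <- c(-40, -30, -20, -15, -10, 10, 15, 20, 30, 40)
  qm <- quadrant_map(g, g)
  margin <- 5

  expect_true(all(qm$dG[qm$quadrant == "I"] >= 0))
  expect_true(all(qm$dG[qm$quadrant == "III"] <= 0))

  q2 <- qm[qm$quadrant == "II", ]
  expect_true(all(q2$dG[abs(q2$dt1) < abs(q2$dt2) - margin] < 0))
  expect_true(all(q2$dG[abs(q2$dt1) > abs(q2$dt2) + margin] > 0))

  q4 <- qm[qm$quadrant == "IV", ]
  # depression on and near the |dt1| = |dt2| diagonal: no sign crossover
  expect_true(all(q4$dG[abs(abs(q4$dt1) - abs(q4$dt2)) <= margin] < 0))
  # and in the |dt1| > |dt2| region
  expect_true(all(q4$dG[abs(q4$dt1) > abs(q4$dt2) + margin] < 0))
  # both signs are present in quadrant IV (potentiation away from the diagonal)
  expect_gt(sum(q4$dG > 0), 0)

  expect_equal(unique(q2$ordering), "post-pre-post")
  expect_equal(unique(q4$ordering), "pre-post-pre")
  expect_error(quadrant_map(c(0, 10), g), "exclude 0")
})

test_that("triplet parameter fitting round-trips and reports violations", {
  truth <- triplet_params(A2_plus = 0.6, A2_minus = 1.3, A3_plus = 1.6,
                          A3_minus = 0.2, tau_plus = 14, tau_minus = 40,
                          tau_x = 80, tau_y = 110, tau_supp = 20)
  g1 <- c(-35, -25, -15, -8, 8, 15, 25, 35)
  obs <- quadrant_map(g1, g1, truth)
  obs <- obs[obs$quadrant %in% c("II", "IV"), c("dt1", "dt2", "dG")]

  fit <- fit_triplet_params(obs, start = triplet_params(tau_supp = 20))
  expect_true(fit$constraint_ok)
  expect_lt(fit$residual, 1e-4)
  for (nm in c("A2_plus", "A2_minus", "A3_plus", "tau_plus", "tau_minus")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 0.02,
                 label = nm)
  }

  # 5% observation noise: amplitudes recovered within 15%
  set.seed(8)
  obs_noisy <- obs
  obs_noisy$dG <- obs$dG * (1 + rnorm(nrow(obs), 0, 0.05))
  fitn <- fit_triplet_params(obs_noisy, start = triplet_params(tau_supp = 20))
  for (nm in c("A2_plus", "A2_minus", "A3_plus")) {
    expect_equal(fitn$params[[nm]], truth[[nm]], tolerance = 0.15, label = nm)
  }

  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_true(glance(fit)$constraint_ok)
})

test_that("fitting rejects underdetermined observation sets", {
  g1 <- c(-30, -20, -10, 10, 20, 30)
  full <- quadrant_map(g1, g1)
  q2_only <- full[full$quadrant == "II", c("dt1", "dt2", "dG")]
  expect_gte(nrow(q2_only), 8)
  expect_error(fit_triplet_params(q2_only), "span quadrants")
  expect_error(fit_triplet_params(q2_only[1:4, ]), "at least 8")
})

test_that("data from a threshold-violating kernel triggers the constraint warning", {
  bad <- suppressWarnings(
    triplet_params(A2_plus = 2.0, A2_minus = 0.3, A3_plus = 1.5,
                   A3_minus = 0.1, tau_supp = 20)
  )
  g1 <- c(-35, -25, -15, -8, 8, 15, 25, 35)
  obs <- quadrant_map(g1, g1, bad)
  obs <- obs[obs$quadrant %in% c("II", "IV"), c("dt1", "dt2", "dG")]
  expect_warning(fit <- fit_triplet_params(obs, start = triplet_params(tau_supp = 20)),
                 "positive BCM threshold")
  expect_false(fit$constraint_ok)
})
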