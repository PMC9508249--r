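test_that("phi has the exact BCM sign structure", {
  p <- bcm_params()
  expect_identical(phi(0, 10, p), 0)
  expect_equal(phi(10, 10, p), 0)
  expect_lt(phi(5, 10, p), 0)
  expect_gt(phi(20, 10, p), 0)
  expect_error(phi(-1, 10, p), ">= 0")
})

test_that("phi sign structure holds over random valid parameter sets", {
  set.seed(17)
  for (i in 1:50) {
    tri <- random_valid_triplet()
    p <- bcm_params(triplet = tri, rho0 = runif(1, 5, 50))
    theta <- runif(1, 1, 80)
    expect_identical(phi(0, theta, p), 0)
    expect_equal(phi(theta, theta, p), 0, tolerance = 1e-12)
    below <- runif(1, 1e-6, theta * 0.999)
    above <- theta * runif(1, 1.001, 3)
    expect_lt(phi(below, theta, p), 0)
    expect_gt(phi(above, theta, p), 0)
  }
})

test_that("bcm_dGdt matches direct polynomial arithmetic and factorizes as phi * rho_x", {
  p <- bcm_params()
  tr <- p$triplet
  avg <- 900  # <rho_y^2>, Hz^2
  rho_x <- 10; rho_y <- 2 * slide_theta(avg, p)
  # brute-force evaluation of the quadratic, A3- = 0, pair terms scaled
  ms <- 1e-3
  sc <- avg / p$rho0^2
  want <- (-tr$A2_minus * sc * tr$tau_minus * ms * rho_y +
             tr$A2_plus * sc * tr$tau_plus * ms * rho_y +
             tr$A3_plus * tr$tau_plus * ms * tr$tau_y * ms * rho_y^2) * rho_x
  expect_equal(bcm_dGdt(rho_x, rho_y, avg, p), want)
  expect_gt(want, 0)  # rho_y = 2 theta: potentiation

  # multiplicative in rho_x; zero input, zero change
  expect_identical(bcm_dGdt(0, 50, avg, p), 0)
  expect_equal(bcm_dGdt(c(1, 2, 4), 50, avg, p),
               bcm_dGdt(1, 50, avg, p) * c(1, 2, 4))

  # equivalence with the reduced phi form
  theta <- slide_theta(avg, p)
  expect_equal(bcm_dGdt(rho_x, 37, avg, p), phi(37, theta, p) * rho_x)
  # depression below threshold
  expect_lt(bcm_dGdt(10, 0.5 * theta, avg, p), 0)
})

test_that("the threshold slides proportionally to the squared-rate average", {
  p <- bcm_params()
  expect_identical(slide_theta(0, p), 0)
  t1 <- slide_theta(400, p)
  expect_equal(slide_theta(800, p), 2 * t1)
  # scaling all rates by k scales theta by k^2
  expect_equal(slide_theta(400 * 9, p), 9 * t1)
  expect_gt(t1, 0)
})

test_that("threshold stored in the device history state increases with G0", {
  th <- history_theta(c(100, 200, 300))
  expect_true(all(diff(th) > 0))
})

test_that("the second-moment average is an EMA with the right step response", {
  p <- bcm_params(tau_avg = 1000)
  st <- bcm_state(rep(0.02, 4), p, probe_rho_y = 0)
  expect_equal(st$theta, 0)

  # one tau_avg after a step, the average covers 1 - 1/e of the gap
  st1 <- update_average(st, 30, 1000)
  expect_equal(st1$avg_rho_y_sq, 900 * (1 - exp(-1)))

  # held long: average converges to rho_y^2, theta to slide_theta of it
  for (i in 1:20) st <- update_average(st, 30, 1000)
  expect_equal(st$avg_rho_y_sq, 900, tolerance = 1e-8)
  expect_equal(st$theta, slide_theta(st$avg_rho_y_sq, p))

  # silence forever: theta drains to 0
  for (i in 1:50) st <- update_average(st, 0, 1000)
  expect_lt(st$theta, 1e-6)
})

test_that("bcm_step clips weights and respects dimensions", {
  p <- bcm_params()
  st <- bcm_state(rep(p$w_min, 5), p, probe_rho_y = 60)
  expect_error(bcm_step(st, rep(10, 4), 200), "mismatch")

  # rho_y far below theta at the lower bound: clipping holds the floor
  st2 <- bcm_step(st, rep(10, 5), 200)
  expect_true(all(st2$w == p$w_min))

  # rho_y pinned above theta (rho0 large keeps theta low): weight rises
  # monotonically to the bound
  p3 <- bcm_params(w_min = 0.01, w_max = 0.08, rho0 = 80,
                   triplet = scale_triplet(triplet_params(A3_minus = 0,
                                                          tau_supp = 0), 1e-3))
  st3 <- bcm_state(0.05, p3, probe_rho_y = 10)
  w_prev <- st3$w
  for (i in 1:2000) {
    st3 <- bcm_step(st3, 30, 200, rho_y = 60)
    expect_gte(st3$w, w_prev - 1e-12)
    w_prev <- st3$w
  }
  expect_gt(st3$theta, 0)
  expect_gt(60, st3$theta)  # stays superthreshold throughout
  expect_equal(st3$w, 0.08)
})

test_that("a single driven synapse converges to the BCM fixed point rho_y = theta", {
  p <- bcm_params(w_min = 0.1, w_max = 8,
                  triplet = scale_triplet(triplet_params(A3_minus = 0, tau_supp = 0), 2e-4))
  tr <- p$triplet
  ms <- 1e-3
  # analytic fixed point of the self-consistent threshold
  rho_star <- p$rho0^2 * tr$A3_plus * tr$tau_plus * ms * tr$tau_y * ms /
    (tr$A2_minus * tr$tau_minus * ms - tr$A2_plus * tr$tau_plus * ms)
  st <- bcm_state(0.5, p, probe_rho_y = 0.5 * 30)
  for (i in 1:4000) st <- bcm_step(st, 30, 200)
  expect_equal(st$last_rho_y, rho_star, tolerance = 0.01)
  expect_equal(st$last_rho_y, st$theta, tolerance = 0.01)
  # and the weight has stopped moving (no oscillation beyond tolerance)
  w_before <- st$w
  for (i in 1:100) st <- bcm_step(st, 30, 200)
  expect_equal(st$w, w_before, tolerance = 1e-3)
})

test_that("rate-based dG/dt agrees with the event-driven triplet simulation", {
  # cross-module oracle: on independent Poisson trains, the BCM polynomial
  # (with the pair-term rescaling frozen at avg = rho0^2) must equal the
  # Monte-Carlo mean drift of the spike-based rule
  tri <- triplet_params(A3_minus = 0, tau_supp = 0)
  p <- bcm_params(triplet = tri)
  set.seed(5)
  rho_x <- 15; rho_y <- 20
  mc <- mc_dwdt(rho_x, rho_y, tri, chunk_ms = 4e4, n_chunks = 40)
  rate_based <- bcm_dGdt(rho_x, rho_y, p$rho0^2, p)
  expect_lt(abs(mc$mean - rate_based) / mc$se, 3)
})

test_that("bcm parameter invariants are enforced", {
  expect_error(bcm_params(rho0 = 0), "rho0")
  expect_error(bcm_params(triplet = triplet_params(A3_minus = 0.2)), "A3_minus")
  bad <- suppressWarnings(triplet_params(A2_plus = 2, A2_minus = 0.5, A3_minus = 0))
  expect_error(bcm_params(triplet = bad), "positive BCM threshold")
  expect_error(slide_theta(-1, bcm_params()), ">= 0")
})
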