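test_that("the first comparison case reproduces its stationary frequencies", {
  p <- case1_params()
  sol <- solve_stationary_2region(p, space = space2)
  expect_equal(unname(sol$pi_hat), c(0.057, 0.506, 0.437), tolerance = 0.002)

  ode <- integrate_frequency_ode(p, space2, rep(1 / 3, 3), 400, 801)
  expect_equal(unname(attr(ode, "terminal")), unname(sol$pi_hat),
               tolerance = 1e-8)

  # the closed-form constants printed for the A component agree with eigen
  expect_equal(sol$numA / sol$denomA, unname(sol$pi_hat[1]), tolerance = 1e-12)
  # stationarity of the reduced system: the per-capita balances of the two
  # endemic states vanish at the fixed point (the widespread state's balance
  # is eliminated by the simplex reduction and is not zero in general)
  resid <- stationary_rate_residuals(p, sol$pi_hat, space2)
  expect_lt(max(abs(resid$residual[1:2])), 1e-8)
})

test_that("the second comparison case puts most mass on the widespread state", {
  fx <- sse_fixture("stationary_case2")
  sol <- solve_stationary_2region(fx$params, space = space2)
  expect_equal(unname(sol$pi_hat[3]), 0.8008, tolerance = 0.005)
  expect_equal(unname(sol$pi_hat[1]), 0.0996, tolerance = 0.005)
})

test_that("symmetric rates give symmetric deterministic trajectories", {
  ps <- params2(0.05, 0.05, 0.02, 0.02, 0.03, 0.03, 0.01)
  traj <- integrate_frequency_ode(ps, space2, c(0.3, 0.3, 0.4), 100, 201)
  expect_equal(traj$A, traj$B, tolerance = 1e-12)
})

test_that("closed-form trajectories match numerical integration", {
  set.seed(61)
  worst <- 0
  tested <- 0
  while (tested < 60) {
    p <- random_params(space2, lo = 1e-3, hi = 1)
    pi0 <- c(0.3, 0.3, 0.4)
    sol <- solve_stationary_2region(p, pi0 = pi0, space = space2)
    times <- seq(0, 40, length.out = 8001)
    cf <- suppressWarnings(stationary2_trajectory(sol, times))
    # the closed form only claims the region where Pi_A + Pi_B <= 1; saddle
    # rate sets whose trajectories leave the simplex are outside it
    if (!isTRUE(attr(cf, "valid"))) next
    tested <- tested + 1
    ode <- integrate_frequency_ode(p, space2, pi0, 40, 8001)
    worst <- max(worst, max(abs(as.matrix(cf[, -1]) - as.matrix(ode[, -1]))))
  }
  expect_lt(worst, 1e-7)
})

test_that("starting at the fixed point freezes the closed-form solution", {
  p <- case1_params()
  base <- solve_stationary_2region(p, space = space2)
  sol <- solve_stationary_2region(p, pi0 = base$pi_hat, space = space2)
  expect_equal(sol$C1, 0, tolerance = 1e-12)
  expect_equal(sol$C2, 0, tolerance = 1e-12)
  traj <- stationary2_trajectory(sol, seq(0, 50, length.out = 11))
  expect_equal(as.numeric(traj$A), rep(unname(base$pi_hat[1]), 11),
               tolerance = 1e-12)
  # relaxation eigenvalues are negative for a strictly positive rate set
  expect_lt(sol$lambda1, 0)
  expect_lt(sol$lambda2, 0)
  expect_error(solve_stationary_2region(random_params(space3), space = space3),
               "exactly two regions")
})

test_that("the projection-matrix method matches the published comparison", {
  p <- case1_params()
  eig <- stationary_by_eigen(p, space2)
  expect_equal(eig$pi_hat, c(0.055, 0.490, 0.455), tolerance = 0.003)
  expect_equal(sum(eig$pi_hat), 1)

  # one-state system is trivially at frequency one
  sp1 <- enumerate_range_states("A")
  p1 <- validate_params(geosse_params(w = c(A = 0.1), e = c(A = 0.05)), sp1)
  expect_equal(stationary_by_eigen(p1, sp1)$pi_hat, 1)

  # a transition-only binary chain has the two-state Markov stationary law
  bp <- bisse_params(0, 0, 0, 0, q12 = 0.3, q21 = 0.1)
  expect_equal(stationary_by_eigen(bp)$pi_hat,
               c(0.1 / 0.4, 0.3 / 0.4), tolerance = 1e-10)
})

test_that("eigen and ODE stationary frequencies agree to the published precision", {
  for (nm in c("stationary_case1", "stationary_case2")) {
    fx <- sse_fixture(nm)
    ode_term <- attr(integrate_frequency_ode(fx$params, space2, rep(1 / 3, 3),
                                             2000, 2001), "terminal")
    eig <- stationary_by_eigen(fx$params, space2)
    # the two published methods themselves differ by up to 0.018 per state
    expect_lt(max(abs(unname(ode_term) - eig$pi_hat)), 0.02)
  }
})

test_that("mixing times hit the published grid values", {
  f9 <- sse_fixture("thirds_family1_b")
  t9 <- time_to_stationarity(f9$params, space2, f9$init$frequencies,
                             t_max = 250, n_grid = 1000, epsilon = 1e-9)
  expect_equal(t9$t_star, c(76.827, 75.576, 70.320), tolerance = 0.0075)
  expect_equal(attr(t9, "delta_t"), 250 / 999)

  f10 <- sse_fixture("thirds_family2_a")
  t10 <- time_to_stationarity(f10$params, space2, f10$init$frequencies,
                              t_max = 60, n_grid = 1000, epsilon = 1e-9)
  expect_equal(t10$t_star, c(53.153, 51.952, 48.048), tolerance = 0.0026)
})

test_that("mixing-time edge cases resolve on the first grid step", {
  p <- case1_params()
  pi_hat <- solve_stationary_2region(p, space = space2)$pi_hat
  dt <- 100 / 499
  # starting at stationarity: converged at the first testable grid point
  t_fix <- time_to_stationarity(p, space2, pi_hat, 100, 500, epsilon = 1e-9)
  expect_equal(t_fix$t_star, rep(dt, 3))
  # an enormous epsilon is met immediately
  t_eps <- time_to_stationarity(p, space2, c(0.2, 0.3, 0.5), 100, 500,
                                epsilon = 10)
  expect_equal(t_eps$t_star, rep(dt, 3))
  # an impossible horizon is reported per state
  expect_warning(
    t_na <- time_to_stationarity(p, space2, c(0.2, 0.3, 0.5), 0.5, 50,
                                 epsilon = 1e-12),
    "never reached"
  )
  expect_true(all(!t_na$converged))
})

test_that("three-region deterministic dynamics stay on the simplex and meet the eigen method", {
  fx <- sse_fixture("example4")
  # the growth-compensated field is tangent to the simplex, so row sums are
  # conserved by the dynamics (not by construction) ...
  traj <- integrate_frequency_ode(fx$params, fx$space, rep(1 / 7, 7),
                                  1500, 1501, variant = "per-capita")
  vals <- as.matrix(traj[, -1])
  expect_equal(rowSums(vals), rep(1, nrow(vals)), tolerance = 1e-9)
  # ... and its attracting fixed point is the stable stage distribution
  term <- attr(traj, "terminal")
  eig <- stationary_by_eigen(fx$params, fx$space)
  expect_equal(unname(term), eig$pi_hat, tolerance = 1e-6)
})
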