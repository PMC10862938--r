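test_that("a silent model yields constant trajectories under every simulator", {
  p0 <- params2(0, 0, 0, 0, 0, 0, 0)
  n0 <- c(A = 7, B = 3, AB = 2)
  for (traj in list(
    simulate_count_path(p0, space2, n0, 5, 50, seed = 1),
    simulate_jump_process(p0, space2, n0, 5, seed = 1)
  )) {
    vals <- traj[, c("A", "B", "AB")]
    expect_true(all(vals$A == 7 & vals$B == 3 & vals$AB == 2))
  }
  fr <- simulate_frequency_path(p0, space2, n0, 5, 50, seed = 1)
  expect_equal(unname(as.matrix(fr[nrow(fr), -1])), matrix(c(7, 3, 2) / 12, 1))
})

test_that("the count diffusion clamps negative excursions to exactly zero", {
  # strong extinction drives counts negative within a coarse step
  p <- params2(0, 0, 5, 5, 1e-4, 1e-4, 1e-4)
  traj <- suppressWarnings(
    simulate_count_path(p, space2, c(2, 2, 2), 10, 20, seed = 5)
  )
  vals <- as.matrix(traj[, -1])
  expect_true(all(vals >= 0))
  expect_true(any(vals == 0))
})

test_that("the count diffusion reproduces the linear-birth expectation", {
  sp1 <- enumerate_range_states("A")
  p <- validate_params(geosse_params(w = c(A = 0.1), e = c(A = 0)), sp1)
  ens <- suppressWarnings(ensemble(
    function(seed) simulate_count_path(p, sp1, 100, 10, 400, seed = seed),
    replicates = 300, seed = 31
  ))
  target <- 100 * exp(1)
  se <- sqrt(ens$summary$variance / 300)
  expect_lt(abs(ens$summary$mean - target), 3 * se)
})

test_that("frequency paths stay on the simplex and report total extinction", {
  fx <- sse_fixture("thirds_family1_a")
  n0 <- initial_counts(200, fx$init$frequencies, space2)
  traj <- suppressWarnings(
    simulate_frequency_path(fx$params, space2, n0, 20, 400, seed = 7)
  )
  vals <- as.matrix(traj[, -1])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(rowSums(vals), rep(1, nrow(vals)), tolerance = 1e-9)

  doomed <- params2(0, 0, 10, 10, 1e-4, 1e-4, 1e-4)
  expect_error(
    suppressWarnings(
      simulate_frequency_path(doomed, space2, c(1, 1, 0), 50, 500, seed = 8)
    ),
    class = "diffsse_total_extinction"
  )
})

test_that("the jump process matches birth-death closed forms", {
  sp1 <- enumerate_range_states("A")
  # pure death from a single lineage: mean extinction time 1 / e
  pd <- validate_params(geosse_params(w = c(A = 0), e = c(A = 1)), sp1)
  set.seed(41)
  ext <- replicate(1500, {
    tr <- simulate_jump_process(pd, sp1, 1, 30)
    tr$time[nrow(tr) - 1]
  })
  expect_lt(abs(mean(ext) - 1), 3 * stats::sd(ext) / sqrt(1500))

  # pure birth: Yule expectation N0 exp(w t)
  pb <- validate_params(geosse_params(w = c(A = 0.1), e = c(A = 0)), sp1)
  ens <- ensemble(function(seed) simulate_jump_process(pb, sp1, 100, 10, seed = seed),
                  replicates = 300, seed = 42)
  se <- sqrt(ens$summary$variance / 300)
  expect_lt(abs(ens$summary$mean - 100 * exp(1)), 3 * se)
})

test_that("jump events change the total count by at most one", {
  set.seed(43)
  p <- random_params(space3, lo = 0.01, hi = 0.1)
  traj <- simulate_jump_process(p, space3, rep(5, 7), 10, seed = 44)
  totals <- rowSums(as.matrix(traj[, -1]))
  steps <- diff(totals)[seq_len(nrow(traj) - 2)] # last row repeats the state at T
  expect_true(all(steps %in% c(-1, 0, 1)))
  # per-state jumps are single units except the split's paired daughters
  per_state <- abs(diff(as.matrix(traj[, -1])))
  expect_true(all(per_state <= 1))
})

test_that("survival conditioning rejects extinct paths", {
  sp1 <- enumerate_range_states("A")
  pd <- validate_params(geosse_params(w = c(A = 0.2), e = c(A = 1)), sp1)
  traj <- simulate_jump_process(pd, sp1, 2, 4, seed = 45,
                                condition_on_survival = TRUE)
  expect_gt(traj[[nrow(traj), "A"]], 0)
  expect_gte(attr(traj, "rejections"), 1)
})

test_that("simulations are reproducible from their seed", {
  p <- case1_params()
  a <- suppressWarnings(simulate_count_path(p, space2, c(10, 10, 10), 5, 200, seed = 99))
  b <- suppressWarnings(simulate_count_path(p, space2, c(10, 10, 10), 5, 200, seed = 99))
  expect_identical(a, b)
  ja <- simulate_jump_process(p, space2, c(10, 10, 10), 5, seed = 99)
  jb <- simulate_jump_process(p, space2, c(10, 10, 10), 5, seed = 99)
  expect_identical(ja, jb)
})

test_that("ensembles summarize terminal values with valid intervals", {
  p0 <- params2(0, 0, 0, 0, 0, 0, 0)
  ens <- ensemble(function(seed) simulate_count_path(p0, space2, c(4, 5, 6), 2, 20, seed = seed),
                  replicates = 5, seed = 3)
  expect_equal(ens$summary$mean, c(4, 5, 6))
  expect_equal(ens$summary$variance, c(0, 0, 0))
  expect_equal(ens$summary$lower, ens$summary$upper)

  expect_error(ensemble(function(seed) NULL, replicates = 1), "at least 2")

  # the summary mean is the plain average of the terminal draws
  p <- case1_params()
  ens2 <- suppressWarnings(
    ensemble(function(seed) simulate_count_path(p, space2, c(10, 10, 10), 2, 50, seed = seed),
             replicates = 20, seed = 6)
  )
  expect_equal(ens2$summary$mean, unname(colMeans(as.matrix(ens2$terminal))))
  expect_true(all(ens2$summary$lower <= ens2$summary$mean &
                    ens2$summary$mean <= ens2$summary$upper))
})

test_that("jump-process means track the linear mean ODE in the full-event scenario", {
  # the expected counts of the exact process obey dE[N]/dt = A E[N]; the
  # diffusion's drift matrix doubles as an independent mean oracle here
  fx <- sse_fixture("example4")
  n0 <- initial_counts(fx$init$total, fx$init$frequencies, fx$space)
  A <- attr(stationary_by_eigen(fx$params, fx$space), "matrix")
  m <- as.numeric(n0)
  h <- 10 / 4000
  for (s in 1:4000) { # RK4 on the mean ODE
    k1 <- A %*% m; k2 <- A %*% (m + h / 2 * k1)
    k3 <- A %*% (m + h / 2 * k2); k4 <- A %*% (m + h * k3)
    m <- as.numeric(m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  ens <- ensemble(function(seed) simulate_jump_process(fx$params, fx$space, n0,
                                                       10, seed = seed),
                  replicates = 400, seed = 61)
  se <- sqrt(ens$summary$variance / 400)
  expect_true(all(abs(ens$summary$mean - m) < 4 * se + 1e-9))
})

test_that("diffusion and jump ensembles share terminal means in the large-count regime", {
  # all states initialized well above zero, where the Gaussian approximation
  # (and its zero-clamp) is faithful to the exact process
  p <- params2(0.05, 0.04, 0.01, 0.02, 0.02, 0.03, 0.02)
  n0 <- c(A = 30, B = 30, AB = 30)
  dif <- suppressWarnings(ensemble(
    function(seed) simulate_count_path(p, space2, n0, 10, 500, seed = seed),
    replicates = 400, seed = 51
  ))
  jmp <- ensemble(
    function(seed) simulate_jump_process(p, space2, n0, 10, seed = seed),
    replicates = 400, seed = 52
  )
  cmp <- compare_ensembles(dif, jmp, alpha = 0.01)
  expect_true(all(cmp$p_mean > 0.01))
})

test_that("initial counts realize caption frequencies exactly", {
  n <- initial_counts(40, rep(1 / 7, 7), space3)
  expect_equal(sum(n), 40)
  expect_true(all(n %in% c(5, 6)))
  n2 <- initial_counts(40, c(0, 0, 0, 0.25, 0.25, 0.25, 0.25), space3)
  expect_equal(unname(n2), c(0, 0, 0, 10, 10, 10, 10))
  nm <- initial_counts(40, rep(1 / 7, 7), space3, method = "multinomial", seed = 9)
  expect_equal(sum(nm), 40)
})
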