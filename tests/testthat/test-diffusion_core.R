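test_that("count drift/variance follow the BiSSE closed forms", {
  bp <- bisse_params(lambda1 = 0.3, lambda2 = 0.2, mu1 = 0.1, mu2 = 0.05,
                     q12 = 0.02, q21 = 0.07)
  n <- c(25, 13)
  cp <- count_params(bisse_components(n, bp, 1))
  expect_equal(cp$mu, (0.3 - 0.1 - 0.02) * 25 + 0.07 * 13)
  expect_equal(cp$sigma2, (0.3 + 0.1 + 0.02) * 25 + 0.07 * 13)

  # balanced gains and losses: zero drift, variance twice the gain rate
  comp <- tibble::tibble(state = "x", plus_total = 3.2, minus_total = 3.2)
  cp2 <- count_params(comp)
  expect_equal(cp2$mu, 0)
  expect_equal(cp2$sigma2, 6.4)
})

test_that("count parameters compose with the event-rate oracle", {
  set.seed(21)
  p <- random_params(space2)
  n <- c(A = 10, B = 10, AB = 10)
  cp <- count_params(event_rate_components(n, p, space2))
  want <- oracle_components(n, p, space2)
  expect_equal(cp$mu, want$plus_total - want$minus_total, tolerance = 1e-12)
  expect_equal(cp$sigma2, want$plus_total + want$minus_total, tolerance = 1e-12)
  # the variance always dominates the drift in magnitude
  for (rep in 1:50) {
    cp_r <- count_params(event_rate_components(random_counts(space2),
                                               random_params(space2), space2))
    expect_true(all(cp_r$sigma2 >= abs(cp_r$mu)))
  }
})

test_that("the one-dimensional Ito transform follows the chain rule", {
  expect_equal(ito_transform(1.5, 2.5, 1, 0), list(mu = 1.5, sigma2 = 2.5))
  expect_equal(ito_transform(1.5, 2.5, 2, 0), list(mu = 3, sigma2 = 10))
  # g(z) = z^2 at z = 3, mu = 1, sigma2 = 2: mu_Y = 6 + 2 = 8, var_Y = 72
  expect_equal(ito_transform(1, 2, g1 = 2 * 3, g2 = 2),
               list(mu = 8, sigma2 = 72))
})

test_that("the multivariate transform sums independent components", {
  mu <- c(0.4, -0.2, 0.1)
  s2 <- c(1, 2, 3)
  # X = sum of the components
  tot <- multivariate_ito(rep(1, 3), rep(0, 3), mu, s2)
  expect_equal(tot$mu, sum(mu))
  expect_equal(tot$sigma2, sum(s2))
  # single component reduces to the univariate transform
  one <- multivariate_ito(2, 0.5, 0.4, 1)
  expect_equal(one, ito_transform(0.4, 1, 2, 0.5))
  expect_error(multivariate_ito(c(1, 1), 0, 0, 0), "equal length")
})

test_that("frequency diffusion parameters equal the Ito transform of n_i / N", {
  set.seed(22)
  for (space in list(space2, space3)) {
    for (rep in 1:50) {
      p <- random_params(space)
      n <- as.numeric(random_counts(space))
      cp <- count_params(event_rate_components(n, p, space))
      fp <- frequency_params(cp, n)
      N <- sum(n)
      for (i in seq_along(n)) {
        # analytic partials of Pi_i = n_i / N, derived independently
        d1 <- (as.numeric(seq_along(n) == i) - n[i] / N) / N
        d2 <- -2 * as.numeric(seq_along(n) == i) / N^2 + 2 * n[i] / N^3
        ref <- multivariate_ito(d1, d2, cp$mu, cp$sigma2)
        expect_equal(fp$mu_pi[i], ref$mu, tolerance = 1e-10)
        expect_equal(fp$sigma2_pi[i], ref$sigma2, tolerance = 1e-10)
      }
    }
  }
})

test_that("frequency parameters are undefined at total extinction", {
  cp <- tibble::tibble(state = c("A", "B", "AB"), mu = 0, sigma2 = 0)
  expect_error(frequency_params(cp, c(0, 0, 0)), "total extinction")
  # an all-quiet process has zero frequency drift and variance
  fp <- frequency_params(cp, c(5, 5, 5))
  expect_true(all(fp$mu_pi == 0) && all(fp$sigma2_pi == 0))
})

test_that("equal-thirds family rates have zero deterministic drift at one third", {
  p <- rate_family_thirds(1, bBA = 0.004, dAB = 0.015, dBA = 0.173, eB = 0.008)
  # the family fixes wA = (-2 bBA + 2 dAB + dBA - 2 eB) / 2 = 0.0895
  expect_equal(p$w[["A"]], 0.0895)
  expect_equal(p$e[["A"]], 0.176)
  dr <- large_N_frequency_drift(rep(1 / 3, 3), p, space2)
  expect_equal(dr$drift, rep(0, 3), tolerance = 1e-12)

  p0 <- params2(0, 0, 0, 0, 0, 0, 0)
  expect_true(all(large_N_frequency_drift(c(0.2, 0.3, 0.5), p0, space2)$drift == 0))
})

test_that("finite-N frequency drift and variance converge at rate 1/N", {
  # the plain per-capita difference is the exact limit of the finite-N drift
  # only where every state's gains and losses balance; random members of the
  # equal-thirds families provide such fully balanced rate sets
  set.seed(23)
  for (rep in 1:16) {
    p <- sample_rate_family_thirds(1 + rep %% 2)
    target <- rep(1 / 3, 3)
    limit <- large_N_frequency_drift(target, p, space2)$drift
    expect_equal(limit, rep(0, 3), tolerance = 1e-14)
    err_at <- function(N) {
      cp <- count_params(event_rate_components(N * target, p, space2))
      fp <- frequency_params(cp, N * target)
      list(mu = max(abs(fp$mu_pi - limit)), s2 = max(fp$sigma2_pi))
    }
    e1 <- err_at(1e4)
    e2 <- err_at(2e4)
    expect_gt(e1$mu / e2$mu, 1.8)
    expect_lt(e1$mu / e2$mu, 2.2)
    expect_gt(e1$s2 / e2$s2, 1.8)
    expect_lt(e1$s2 / e2$s2, 2.2)
  }
})

test_that("the growth-compensated drift is the finite-N limit at generic frequencies", {
  set.seed(24)
  for (rep in 1:10) {
    p <- random_params(space2)
    pi <- c(0.5, 0.3, 0.2)
    limit <- large_N_frequency_drift(pi, p, space2, variant = "per-capita")$drift
    err_at <- function(N) {
      cp <- count_params(event_rate_components(N * pi, p, space2))
      max(abs(frequency_params(cp, N * pi)$mu_pi - limit))
    }
    ratio <- err_at(1e4) / err_at(2e4)
    expect_gt(ratio, 1.8)
    expect_lt(ratio, 2.2)
  }
})
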