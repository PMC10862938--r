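#' Infinitesimal drift and variance of the count process
#'
#' For each state, the count diffusion has drift equal to the gain rate minus
#' the loss rate and variance equal to their sum.  Accepts the component
#' tibble produced by [event_rate_components()] or [bisse_components()]
#' (anything with `plus_total` and `minus_total` columns).
#'
#' @param components A tibble with columns `state`, `plus_total`,
#'   `minus_total`.
#' @return A tibble with columns `state`, `mu`, `sigma2`.
#' @examples
#' space <- enumerate_range_states(c("A", "B"))
#' pars <- validate_params(geosse_params(
#'   w = c(A = 0.01, B = 0.02), e = c(A = 0.169, B = 0.008),
#'   d = c("A>B" = 0.002, "B>A" = 0.178), b = c("A|B" = 0.003)
#' ), space)
#' count_params(event_rate_components(c(10, 10, 10), pars, space))
#' @export
count_params <- function(components) {
  if (!all(c("plus_total", "minus_total") %in% names(components))) {
    rlang::abort("`components` needs `plus_total` and `minus_total` columns.")
  }
  tibble::tibble(
    state = components$state,
    mu = components$plus_total - components$minus_total,
    sigma2 = components$plus_total + components$minus_total
  )
}

# drift/variance of the count process straight from counts and params
count_diffusion <- function(counts, params, space) {
  count_params(event_rate_components(counts, params, space))
}

#' Ito transformation of a one-dimensional diffusion
#'
#' Given a diffusion with drift `mu` and variance `sigma2`, the transformed
#' process `Y = g(Z)` has drift `mu * g'(z) + sigma2 * g''(z) / 2` and
#' variance `sigma2 * g'(z)^2`.  Derivative values are supplied at the
#' current point, so the function is vectorized over states.
#'
#' @param mu,sigma2 Drift and variance of the original process.
#' @param g1,g2 First and second derivative of the transform at the current
#'   value.
#' @return A list with elements `mu` and `sigma2` of the transformed process.
#' @export
ito_transform <- function(mu, sigma2, g1, g2) {
  stopifnot(all(is.finite(c(mu, sigma2, g1, g2))))
  list(mu = mu * g1 + 0.5 * sigma2 * g2, sigma2 = sigma2 * g1^2)
}

#' Multivariate Ito transformation with independent components
#'
#' Drift and variance of a scalar function `X(n_1, ..., n_k)` of independent
#' component diffusions: cross-covariances are assumed zero (the component
#' birth-death processes are modelled as independent), so only the diagonal
#' second-derivative terms enter.
#'
#' @param partials First partial derivatives of `X` with respect to each
#'   component, evaluated at the current point.
#' @param second_partials Second (diagonal) partial derivatives.
#' @param mu,sigma2 Per-component drift and variance vectors.
#' @return A list with scalar elements `mu` and `sigma2`.
#' @export
multivariate_ito <- function(partials, second_partials, mu, sigma2) {
  k <- length(partials)
  if (length(second_partials) != k || length(mu) != k || length(sigma2) != k) {
    rlang::abort("All inputs to `multivariate_ito()` must have equal length.")
  }
  list(
    mu = sum(partials * mu) + 0.5 * sum(second_partials * sigma2),
    sigma2 = sum(partials^2 * sigma2)
  )
}

#' Infinitesimal drift and variance of the frequency process
#'
#' Transforms count-process parameters into parameters of the state-frequency
#' process `Pi_i = N_i / N` via the multivariate Ito formula:
#' \deqn{\mu_{\Pi_i} = \frac{1}{N}\left(\mu_i - \frac{\sigma_i^2}{N}\right) +
#'   \frac{\Pi_i}{N}\sum_j\left(-\mu_j + \frac{\sigma_j^2}{N}\right),}
#' \deqn{\sigma^2_{\Pi_i} = \left(\frac{\sigma_i}{N}\right)^2 (1 - 2\Pi_i) +
#'   \left(\frac{\Pi_i}{N}\right)^2 \sum_j \sigma_j^2.}
#' Undefined at total extinction (`N = 0`), which is reported as an error.
#'
#' @param count_params Tibble from [count_params()]: columns `state`, `mu`,
#'   `sigma2`.
#' @param counts Per-state counts used to form `N` and the frequencies.
#' @return A tibble with columns `state`, `mu_pi`, `sigma2_pi`.
#' @export
frequency_params <- function(count_params, counts) {
  mu <- count_params$mu
  sigma2 <- count_params$sigma2
  counts <- as.numeric(counts)
  if (length(counts) != length(mu)) {
    rlang::abort("`counts` must have one entry per state.")
  }
  N <- sum(counts)
  if (N <= 0) {
    rlang::abort(
      "Total count is zero: frequency diffusion parameters are undefined under total extinction."
    )
  }
  pi_i <- counts / N
  correction <- sum(-mu + sigma2 / N)
  tibble::tibble(
    state = count_params$state,
    mu_pi = (mu - sigma2 / N) / N + pi_i * correction / N,
    sigma2_pi = (sigma2 / N^2) * (1 - 2 * pi_i) + pi_i^2 * sum(sigma2) / N^2
  )
}

#' Large-N drift of the frequency process
#'
#' In the infinite-population limit the frequency variance vanishes and the
#' drift reduces to the difference of per-capita gain and loss rates,
#' `mu_hat_i = p_hat_plus_i - p_hat_minus_i`.  This is the drift that defines
#' the deterministic frequency dynamics and all stationary-frequency results.
#'
#' The `"per-capita"` variant subtracts the total net per-capita growth,
#' `pi_i * sum_j (p_hat_plus_j - p_hat_minus_j)`, which is the term the exact
#' finite-N drift retains in the limit when total growth is nonzero.  The two
#' variants coincide at any stationary point.  The canonical behaviour (and
#' the default) is the plain difference.
#'
#' @inheritParams per_capita_rates
#' @param variant `"canonical"` (the plain per-capita difference) or
#'   `"per-capita"` (growth-compensated; for cross-checks against the
#'   eigenvector method).
#' @return A tibble with columns `state` and `drift`.
#' @export
large_N_frequency_drift <- function(freqs, params, space,
                                    variant = c("canonical", "per-capita")) {
  variant <- match.arg(variant)
  pc <- per_capita_rates(freqs, params, space)
  drift <- pc$p_hat_plus - pc$p_hat_minus
  if (variant == "per-capita") {
    pi <- as_state_vector(freqs, space, "frequencies")
    drift <- drift - unname(pi) * sum(drift)
  }
  tibble::tibble(state = pc$state, drift = drift)
}
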