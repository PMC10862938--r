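# ---- deterministic large-N frequency dynamics ------------------------------

# The per-capita count dynamics are linear, dN/dt = A N with A = G - diag(l).
# Substituting the last (full-range) state's frequency as one minus the rest
# gives an affine system for the leading |S|-1 frequencies:
#   dp/dt = M p + cvec,  M[i,j] = A[i,j] - A[i,last],  cvec[i] = A[i,last].
reduced_affine_system <- function(params, space) {
  ops <- rate_operators(params, space)
  k <- nrow(ops$A)
  m <- k - 1L
  A <- ops$A
  M <- A[seq_len(m), seq_len(m), drop = FALSE] -
    matrix(A[seq_len(m), k], m, m)
  cvec <- A[seq_len(m), k]
  list(M = M, cvec = cvec, A = A)
}

#' Integrate the deterministic frequency dynamics
#'
#' Solves the large-N frequency ODE `dPi_i/dt = p_hat_plus_i - p_hat_minus_i`
#' with the last (full-range) state's frequency eliminated as one minus the
#' sum of the others -- the same reduction that underlies the two-region
#' closed form.  Integration uses a fixed-step fourth-order Runge-Kutta
#' scheme on a uniform grid; the terminal row is the stationary estimate once
#' the trajectory has converged.
#'
#' @inheritParams simulate_count_path
#' @param pi0 Initial state frequencies (must sum to 1).
#' @param t_max Integration horizon.
#' @param n_grid Number of grid points on `[0, t_max]` (including both ends).
#' @param variant Drift variant passed to the dynamics: `"canonical"` (the
#'   per-capita gain/loss difference, the default used by all stationary
#'   results) or `"per-capita"` (growth-compensated; integrates the full
#'   simplex-preserving system).
#' @return An `sse_trajectory` of frequencies with attribute `terminal`
#'   holding the final frequencies.
#' @examples
#' space <- enumerate_range_states(c("A", "B"))
#' pars <- validate_params(geosse_params(
#'   w = c(A = 0.01, B = 0.02), e = c(A = 0.169, B = 0.008),
#'   d = c("A>B" = 0.002, "B>A" = 0.178), b = c("A|B" = 0.003)
#' ), space)
#' traj <- integrate_frequency_ode(pars, space, c(1, 1, 1) / 3, 400, 801)
#' attr(traj, "terminal")
#' @export
integrate_frequency_ode <- function(params, space, pi0, t_max, n_grid,
                                    variant = c("canonical", "per-capita")) {
  variant <- match.arg(variant)
  pi0 <- as_state_vector(pi0, space, "initial frequencies")
  if (abs(sum(pi0) - 1) > 1e-9) {
    rlang::abort("`pi0` must sum to 1 (within 1e-9).")
  }
  if (n_grid < 2) rlang::abort("`n_grid` must be at least 2.")
  k <- length(pi0)
  times <- seq(0, t_max, length.out = n_grid)
  if (variant == "canonical") {
    sys <- reduced_affine_system(params, space)
    deriv <- function(p) as.numeric(sys$M %*% p + sys$cvec)
    y <- unname(pi0[-k])
  } else {
    ops <- rate_operators(params, space)
    deriv <- function(p) {
      d <- as.numeric(ops$A %*% p)
      d - p * sum(d)
    }
    y <- unname(pi0)
  }
  path <- matrix(0, n_grid, length(y))
  path[1L, ] <- y
  h <- t_max / (n_grid - 1L)
  for (s in seq_len(n_grid - 1L)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    path[s + 1L, ] <- y
  }
  values <- if (variant == "canonical") cbind(path, 1 - rowSums(path)) else path
  out <- new_trajectory(times, values, space$labels, "frequencies")
  attr(out, "terminal") <- stats::setNames(as.numeric(values[n_grid, ]),
                                           space$labels)
  out
}

#' Closed-form stationary solution of the two-region model
#'
#' For two regions the reduced frequency dynamics in `(Pi_A, Pi_B)` are an
#' affine linear system whose general solution is
#' `Pi(t) = C1 nu1 exp(lambda1 t) + C2 nu2 exp(lambda2 t) + K`, with
#' `Pi_AB(t) = 1 - Pi_A(t) - Pi_B(t)` (valid while `Pi_A + Pi_B <= 1`).  The
#' eigen-decomposition of the system matrix is the authoritative source of
#' the eigenvalues, eigenvector ratios, fixed point and integration
#' constants; the textbook scalar constants (`numA`, `denomA`, `R`, `R1`,
#' `R2`) are evaluated alongside and returned for transparency.  (`R1` is
#' assembled with the coefficient pattern `4 (wA + bBA + eB)(wB + bBA + eA)`
#' that the eigen-decomposition validates.)
#'
#' @param params A validated two-region [geosse_params()].
#' @param pi0 Initial frequencies `(Pi_A, Pi_B, Pi_AB)`; defaults to the
#'   fixed point (so the trajectory is constant).
#' @param space Optional state space; defaults to regions `A`, `B` taken from
#'   `params`.
#' @return An object of class `sse_stationary2`: list with `pi_hat` (named
#'   stationary frequencies), `lambda1`, `lambda2`, `nu1`, `nu2` (eigenvector
#'   ratios `Pi_A`-to-`Pi_B`), `C1`, `C2`, `K`, and the scalar constants
#'   `numA`, `denomA`, `R`, `R1`, `R2`.
#' @examples
#' space <- enumerate_range_states(c("A", "B"))
#' pars <- validate_params(geosse_params(
#'   w = c(A = 0.01, B = 0.02), e = c(A = 0.169, B = 0.008),
#'   d = c("A>B" = 0.002, "B>A" = 0.178), b = c("A|B" = 0.003)
#' ), space)
#' sol <- solve_stationary_2region(pars, pi0 = c(1, 1, 1) / 3, space = space)
#' sol$pi_hat
#' @export
solve_stationary_2region <- function(params, pi0 = NULL, space = NULL) {
  if (is.null(space)) {
    space <- enumerate_range_states(names(params$w))
  }
  if (length(space$regions) != 2L) {
    rlang::abort("The closed form applies to exactly two regions.")
  }
  sys <- reduced_affine_system(params, space)
  M <- sys$M
  cvec <- sys$cvec
  K <- solve(M, -cvec)
  eg <- eigen(M)
  ord <- order(Re(eg$values))          # lambda1 is the more negative root
  lambda <- Re(eg$values)[ord]
  V <- Re(eg$vectors)[, ord, drop = FALSE]
  # normalize each eigenvector to [nu, 1] so nu is the A-to-B component ratio
  nu <- V[1, ] / V[2, ]
  V <- sweep(V, 2, V[2, ], "/")

  rA <- space$regions[1]
  rB <- space$regions[2]
  wA <- params$w[[rA]]; wB <- params$w[[rB]]
  eA <- params$e[[rA]]; eB <- params$e[[rB]]
  dAB <- params$d[[dispersal_key(rA, rB)]]
  dBA <- params$d[[dispersal_key(rB, rA)]]
  bBA <- params$b[[split_key(rA, rB)]]
  numA <- (wA + bBA + eB) * (eB + dBA - wB)
  denomA <- (eA + dAB + bBA + eB) * (eB + dBA + bBA + eA) -
    (wB + bBA + eA) * (wA + bBA + eB)
  R1 <- 4 * (wA + bBA + eB) * (wB + bBA + eA)
  R2 <- dAB^2 + dBA^2 - 2 * dAB * dBA
  R <- sqrt(R1 + R2)

  C <- c(0, 0)
  if (!is.null(pi0)) {
    pi0 <- as_state_vector(pi0, space, "initial frequencies")
    if (abs(sum(pi0) - 1) > 1e-9) {
      rlang::abort("`pi0` must sum to 1 (within 1e-9).")
    }
    C <- solve(V, unname(pi0[1:2]) - K)
  }
  pi_hat <- c(K[1], K[2], 1 - K[1] - K[2])
  structure(
    list(
      pi_hat = stats::setNames(pi_hat, space$labels),
      lambda1 = lambda[1], lambda2 = lambda[2],
      nu1 = nu[1], nu2 = nu[2],
      C1 = C[1], C2 = C[2],
      K = stats::setNames(K, space$labels[1:2]),
      numA = numA, denomA = denomA, R = R, R1 = R1, R2 = R2,
      M = M, cvec = cvec, V = V,
      pi0 = if (is.null(pi0)) NULL else pi0,
      space = space
    ),
    class = "sse_stationary2"
  )
}

#' @export
print.sse_stationary2 <- function(x, ...) {
  cat("<sse_stationary2>\n  stationary frequencies:",
      paste0(names(x$pi_hat), "=", signif(x$pi_hat, 4), collapse = ", "), "\n",
      "  eigenvalues:", signif(x$lambda1, 6), ",", signif(x$lambda2, 6), "\n")
  invisible(x)
}

#' Evaluate the closed-form two-region frequency trajectory
#'
#' @param sol An `sse_stationary2` from [solve_stationary_2region()] built
#'   with an initial condition.
#' @param times Numeric vector of evaluation times.
#' @return An `sse_trajectory` of the three state frequencies.  If
#'   `Pi_A + Pi_B` exceeds 1 anywhere on the requested horizon (outside the
#'   closed form's validity region) the trajectory carries attribute
#'   `valid = FALSE` and a warning is raised.
#' @export
stationary2_trajectory <- function(sol, times) {
  stopifnot(inherits(sol, "sse_stationary2"))
  if (is.null(sol$pi0)) {
    rlang::abort("The solution was built without `pi0`; no trajectory to evaluate.")
  }
  e1 <- exp(sol$lambda1 * times)
  e2 <- exp(sol$lambda2 * times)
  pA <- sol$C1 * sol$V[1, 1] * e1 + sol$C2 * sol$V[1, 2] * e2 + sol$K[1]
  pB <- sol$C1 * sol$V[2, 1] * e1 + sol$C2 * sol$V[2, 2] * e2 + sol$K[2]
  valid <- all(pA + pB <= 1 + 1e-9)
  if (!valid) {
    rlang::warn("Pi_A + Pi_B exceeds 1 on the requested horizon; the two-state reduction is not valid there.")
  }
  out <- new_trajectory(times, cbind(pA, pB, 1 - pA - pB),
                        sol$space$labels, "frequencies")
  attr(out, "valid") <- valid
  out
}

#' Stationary state frequencies by the projection-matrix method
#'
#' Assembles the linear count dynamics `dN/dt = A N` (column `j` holds the
#' per-capita contribution of one state-`j` lineage to each state's drift)
#' and returns the right eigenvector of the eigenvalue with largest real
#' part, normalized to sum one: the stable stage distribution of the
#' projection-matrix model, with the dominant eigenvalue as the overall
#' growth rate.
#'
#' @param params A validated [geosse_params()] object, or a [bisse_params()]
#'   object (for which the two-state linear dynamics are assembled from the
#'   BiSSE components and `space` is ignored).
#' @param space The state space (for GeoSSE parameters).
#' @return A tibble with columns `state` and `pi_hat`, with attributes
#'   `growth_rate` (the dominant eigenvalue) and `matrix`.
#' @export
stationary_by_eigen <- function(params, space = NULL) {
  if (inherits(params, "bisse_params")) {
    cols <- purrr::map(1:2, function(j) {
      n <- c(0, 0)
      n[j] <- 1
      vapply(1:2, function(i) {
        comp <- bisse_components(n, params, i)
        comp$plus_total - comp$minus_total
      }, numeric(1))
    })
    ops <- list(A = matrix(unlist(cols), 2, 2,
                           dimnames = list(c("1", "2"), c("1", "2"))))
    space <- list(states = list("1", "2"), labels = c("1", "2"))
  } else {
    ops <- rate_operators(params, space)
  }
  if (length(space$states) == 1L) {
    out <- tibble::tibble(state = space$labels, pi_hat = 1)
    attr(out, "growth_rate") <- ops$A[1, 1]
    attr(out, "matrix") <- ops$A
    return(out)
  }
  eg <- eigen(ops$A)
  re <- Re(eg$values)
  dom <- which.max(re)
  near <- which(abs(re - re[dom]) < 1e-10 * max(1, abs(re[dom])))
  if (length(near) > 1L || abs(Im(eg$values[dom])) > 1e-10) {
    rlang::abort(
      "Dominant eigenvalue is complex or repeated; the stable stage distribution is not uniquely defined."
    )
  }
  v <- Re(eg$vectors[, dom])
  v <- v * sign(sum(v))
  if (any(v < -1e-10)) {
    rlang::warn("Dominant eigenvector has mixed signs; parameters may be degenerate.")
  }
  out <- tibble::tibble(state = space$labels, pi_hat = v / sum(v))
  attr(out, "growth_rate") <- re[dom]
  attr(out, "matrix") <- ops$A
  out
}

#' Time for each state frequency to reach stationarity
#'
#' Evaluates the deterministic frequency trajectory on a uniform grid and
#' returns, for each state, the first grid time at which the successive
#' change drops below `epsilon`:
#' `t*_i = min { t_k : |Pi_i(t_k) - Pi_i(t_k - dt)| < epsilon }`.
#'
#' @inheritParams integrate_frequency_ode
#' @param epsilon Convergence threshold on the successive change (default
#'   `1e-9`).
#' @param method `"auto"` (closed form for two regions, otherwise the ODE
#'   integrator), `"closed-form"`, or `"ode"`.
#' @return An object of class `sse_mixing_times`: tibble with columns
#'   `state`, `t_star`, `converged`, plus attributes `epsilon` and `delta_t`.
#'   States that never meet the criterion on `[0, t_max]` get `t_star = NA`.
#' @examples
#' space <- enumerate_range_states(c("A", "B"))
#' pars <- validate_params(geosse_params(
#'   w = c(A = 0.160, B = 0.002), e = c(A = 0.315, B = 0.009),
#'   d = c("A>B" = 0.014, "B>A" = 0.310), b = c("A|B" = 0.001)
#' ), space)
#' time_to_stationarity(pars, space, c(0.1, 0.45, 0.45), 250, 1000)
#' @export
time_to_stationarity <- function(params, space, pi0, t_max, n_grid = 1000,
                                 epsilon = 1e-9,
                                 method = c("auto", "closed-form", "ode")) {
  method <- match.arg(method)
  if (epsilon <= 0) rlang::abort("`epsilon` must be positive.")
  if (method == "auto") {
    method <- if (length(space$regions) == 2L) "closed-form" else "ode"
  }
  times <- seq(0, t_max, length.out = n_grid)
  if (method == "closed-form") {
    sol <- solve_stationary_2region(params, pi0 = pi0, space = space)
    traj <- stationary2_trajectory(sol, times)
  } else {
    traj <- integrate_frequency_ode(params, space, pi0, t_max, n_grid)
  }
  vals <- trajectory_values(traj)
  dt <- t_max / (n_grid - 1L)
  hit <- apply(abs(diff(vals)) < epsilon, 2, function(z) {
    i <- which(z)
    if (length(i) == 0) NA_integer_ else i[1] + 1L
  })
  out <- tibble::tibble(
    state = space$labels,
    t_star = unname(ifelse(is.na(hit), NA_real_, times[hit])),
    converged = unname(!is.na(hit))
  )
  if (any(is.na(hit))) {
    rlang::warn(paste0(
      "States never reached the stationarity criterion on [0, ", t_max, "]: ",
      paste(space$labels[is.na(hit)], collapse = ", ")
    ))
  }
  class(out) <- c("sse_mixing_times", class(out))
  attr(out, "epsilon") <- epsilon
  attr(out, "delta_t") <- dt
  out
}
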