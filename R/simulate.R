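# ---- internal machinery ----------------------------------------------------

# The gain totals are linear in the count vector and the loss totals are
# proportional to the state's own count, so the whole rate structure of a
# parameter set collapses to a gain matrix G (plus_total = G %*% n) and a
# per-capita loss vector l (minus_total = l * n).  Built once per run by
# evaluating the event-rate implementation at unit count vectors.
rate_operators <- function(params, space) {
  k <- length(space$states)
  G <- matrix(0, k, k, dimnames = list(space$labels, space$labels))
  l <- stats::setNames(numeric(k), space$labels)
  for (j in seq_len(k)) {
    unit <- stats::setNames(numeric(k), space$labels)
    unit[j] <- 1
    comp <- event_rate_components(unit, params, space)
    G[, j] <- comp$plus_total
    l[j] <- comp$minus_total[j]
  }
  list(G = G, l = l, A = G - diag(l, nrow = k))
}

new_trajectory <- function(times, values, labels, kind, seed = NULL) {
  colnames(values) <- labels
  out <- tibble::as_tibble(as.data.frame(values))
  out <- dplyr::bind_cols(tibble::tibble(time = times), out)
  class(out) <- c("sse_trajectory", class(out))
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  attr(out, "state_labels") <- labels
  out
}

trajectory_values <- function(traj) {
  as.matrix(traj[, attr(traj, "state_labels"), drop = FALSE])
}

terminal_values <- function(traj) {
  v <- trajectory_values(traj)
  stats::setNames(as.numeric(v[nrow(v), ]), colnames(v))
}

#' @export
print.sse_trajectory <- function(x, ...) {
  cat("<sse_trajectory> kind=", attr(x, "kind"),
      ", ", nrow(x), " time points on [", min(x$time), ", ", max(x$time), "]\n",
      sep = "")
  NextMethod()
}

# step-size guidance: per-step event probability should stay small
check_step_size <- function(total_rate, dt) {
  if (is.finite(total_rate) && total_rate * dt > 0.1) {
    rlang::warn(
      paste0(
        "Total event rate times step size is ", signif(total_rate * dt, 3),
        " (> 0.1): consider more time steps so that multiple events per step are unlikely."
      ),
      class = "diffsse_step_warning"
    )
  }
}

# ---- Euler-Maruyama paths --------------------------------------------------

#' Simulate a count trajectory under the diffusion approximation
#'
#' Euler-Maruyama discretization of the per-state count SDE
#' `dN_i = mu_i dt + sigma_i dW_t`: at each step the drift and variance are
#' recomputed from the current counts, each state receives an independent
#' standard-normal increment scaled by `sqrt(dt)`, and any count that falls
#' below zero is clamped to exactly zero.
#'
#' @param params A validated [geosse_params()] object.
#' @param space The state space.
#' @param n0 Initial per-state counts (nonnegative).
#' @param t_max Simulation horizon `T`.
#' @param n_steps Number of Euler steps (`dt = t_max / n_steps`).
#' @param seed RNG seed for reproducibility.
#' @return An `sse_trajectory` tibble (`time` plus one column per state),
#'   with attributes `kind = "counts"` and `seed`.
#' @examples
#' space <- enumerate_range_states(c("A", "B"))
#' pars <- validate_params(geosse_params(
#'   w = c(A = 0.05, B = 0.05), e = c(A = 0.01, B = 0.01),
#'   d = c("A>B" = 0.02, "B>A" = 0.02), b = c("A|B" = 0.01)
#' ), space)
#' traj <- simulate_count_path(pars, space, c(20, 20, 10), t_max = 5,
#'                             n_steps = 500, seed = 1)
#' @export
simulate_count_path <- function(params, space, n0, t_max, n_steps, seed = NULL) {
  n0 <- as_state_vector(n0, space, "initial counts")
  if (any(n0 < 0)) rlang::abort("Initial counts must be nonnegative.")
  if (n_steps < 1) rlang::abort("`n_steps` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  ops <- rate_operators(params, space)
  k <- length(n0)
  dt <- t_max / n_steps
  sqdt <- sqrt(dt)
  values <- matrix(0, n_steps + 1L, k)
  values[1L, ] <- n0
  n <- unname(n0)
  check_step_size(sum(ops$G %*% n + ops$l * n), dt)
  for (s in seq_len(n_steps)) {
    plus <- as.numeric(ops$G %*% n)
    minus <- ops$l * n
    mu <- plus - minus
    sigma <- sqrt(plus + minus)
    n <- n + mu * dt + sigma * sqdt * stats::rnorm(k)
    n[n < 0] <- 0
    values[s + 1L, ] <- n
  }
  new_trajectory(seq(0, t_max, length.out = n_steps + 1L), values,
                 space$labels, "counts", seed)
}

#' Simulate a state-frequency trajectory under the diffusion approximation
#'
#' Follows the coupled scheme: advance the counts by one Euler-Maruyama step,
#' clamp negatives to zero, recompute the total count, form the frequency
#' drift and variance from the (finite-N) frequency diffusion, advance the
#' frequencies with their own independent Wiener increments, then truncate to
#' `[0, 1]` and renormalize so each row sums to one.
#'
#' @inheritParams simulate_count_path
#' @param n0 Initial per-state counts; initial frequencies are `n0 / sum(n0)`.
#' @return An `sse_trajectory` with `kind = "frequencies"`.  If the underlying
#'   count process hits total extinction the simulation aborts with an error
#'   carrying the time at which it happened.
#' @export
simulate_frequency_path <- function(params, space, n0, t_max, n_steps, seed = NULL) {
  n0 <- as_state_vector(n0, space, "initial counts")
  if (any(n0 < 0)) rlang::abort("Initial counts must be nonnegative.")
  if (sum(n0) <= 0) rlang::abort("Initial total count must be positive.")
  if (n_steps < 1) rlang::abort("`n_steps` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  ops <- rate_operators(params, space)
  k <- length(n0)
  dt <- t_max / n_steps
  sqdt <- sqrt(dt)
  values <- matrix(0, n_steps + 1L, k)
  n <- unname(n0)
  p <- n / sum(n)
  values[1L, ] <- p
  check_step_size(sum(ops$G %*% n + ops$l * n), dt)
  for (s in seq_len(n_steps)) {
    plus <- as.numeric(ops$G %*% n)
    minus <- ops$l * n
    mu <- plus - minus
    sigma2 <- plus + minus
    # advance counts first, then build the frequency diffusion from them
    n <- n + mu * dt + sqrt(sigma2) * sqdt * stats::rnorm(k)
    n[n < 0] <- 0
    N <- sum(n)
    if (N <= 0) {
      rlang::abort(
        paste0("Total extinction at time ", signif(s * dt, 6),
               ": frequency diffusion parameters are undefined."),
        class = "diffsse_total_extinction",
        time = s * dt
      )
    }
    plus <- as.numeric(ops$G %*% n)
    minus <- ops$l * n
    mu <- plus - minus
    sigma2 <- plus + minus
    pi_n <- n / N
    correction <- sum(-mu + sigma2 / N)
    mu_pi <- (mu - sigma2 / N) / N + pi_n * correction / N
    sigma2_pi <- (sigma2 / N^2) * (1 - 2 * pi_n) + pi_n^2 * sum(sigma2) / N^2
    sigma2_pi[sigma2_pi < 0] <- 0
    p <- p + mu_pi * dt + sqrt(sigma2_pi) * sqdt * stats::rnorm(k)
    p[p < 0] <- 0
    p[p > 1] <- 1
    if (sum(p) <= 0) p <- pi_n else p <- p / sum(p)
    values[s + 1L, ] <- p
  }
  new_trajectory(seq(0, t_max, length.out = n_steps + 1L), values,
                 space$labels, "frequencies", seed)
}

# ---- exact jump process ----------------------------------------------------

# one row per elementary event; rate = const * n[src]
jump_event_table <- function(params, space) {
  labels <- space$labels
  states <- space$states
  n_regions <- length(space$regions)
  events <- list()
  add <- function(const, src, delta_idx, delta_val) {
    if (const > 0) {
      events[[length(events) + 1L]] <<- list(
        const = const, src = src, idx = delta_idx, val = delta_val
      )
    }
  }
  for (j in seq_along(states)) {
    s_j <- states[[j]]
    # within-region speciation: parent keeps its range, a new endemic appears
    for (l in s_j) {
      add(params$w[[l]], j, match(l, labels), +1)
    }
    # dispersal into a region not yet occupied
    if (length(s_j) < n_regions) {
      for (l in setdiff(space$regions, s_j)) {
        const <- sum(vapply(s_j, function(k) params$d[[dispersal_key(k, l)]],
                            numeric(1)))
        tgt <- match(state_label(c(s_j, l)), labels)
        add(const, j, c(j, tgt), c(-1, +1))
      }
    }
    # between-region speciation: parent replaced by the two daughters
    if (length(s_j) >= 2L) {
      for (sp in enumerate_splits(s_j)) {
        left <- match(state_label(sp$left), labels)
        right <- match(state_label(sp$right), labels)
        add(params$b[[sp$key]], j, c(j, left, right), c(-1, +1, +1))
      }
    }
    # local extinction: drop one region (or the species, if endemic)
    for (l in s_j) {
      rest <- setdiff(s_j, l)
      if (length(rest) == 0L) {
        add(params$e[[l]], j, j, -1)
      } else {
        add(params$e[[l]], j, c(j, match(state_label(rest), labels)), c(-1, +1))
      }
    }
  }
  list(
    const = vapply(events, `[[`, numeric(1), "const"),
    src = vapply(events, `[[`, integer(1), "src"),
    idx = purrr::map(events, "idx"),
    val = purrr::map(events, "val")
  )
}

#' Simulate state counts with the exact Markov jump process
#'
#' Gillespie-style continuous-time simulation of the count vector: every
#' elementary event (within-region speciation, dispersal, between-region
#' speciation, local extinction) fires at its exact rate, waiting times are
#' exponential in the total rate, and each event applies its integer count
#' change.  This is the tree-free equivalent of forward tree simulation and
#' serves as the reference against which the diffusion approximation is
#' validated.
#'
#' @inheritParams simulate_count_path
#' @param n0 Initial per-state counts; must be nonnegative integers.
#' @param condition_on_survival If `TRUE`, paths ending in total extinction
#'   (`N(T) = 0`) are rejected and redrawn; the number of rejected paths is
#'   reported in the `rejections` attribute.
#' @return An `sse_trajectory` recording the state counts at time 0, at every
#'   event time, and at `t_max`.
#' @export
simulate_jump_process <- function(params, space, n0, t_max, seed = NULL,
                                  condition_on_survival = FALSE) {
  n0 <- as_state_vector(n0, space, "initial counts")
  if (any(n0 < 0) || any(abs(n0 - round(n0)) > 1e-8)) {
    rlang::abort("Initial counts for the jump process must be nonnegative integers.")
  }
  n0 <- round(n0)
  if (!is.null(seed)) set.seed(seed)
  ev <- jump_event_table(params, space)
  rejections <- 0L
  repeat {
    times <- 0
    snapshots <- list(unname(n0))
    n <- unname(n0)
    t <- 0
    repeat {
      rates <- ev$const * n[ev$src]
      total <- sum(rates)
      if (total <= 0) break
      t <- t + stats::rexp(1, total)
      if (t >= t_max) break
      pick <- sample.int(length(rates), 1L, prob = rates)
      n[ev$idx[[pick]]] <- n[ev$idx[[pick]]] + ev$val[[pick]]
      times <- c(times, t)
      snapshots[[length(snapshots) + 1L]] <- n
    }
    if (!condition_on_survival || sum(n) > 0) break
    rejections <- rejections + 1L
  }
  times <- c(times, t_max)
  snapshots[[length(snapshots) + 1L]] <- n
  out <- new_trajectory(times, do.call(rbind, snapshots), space$labels,
                        "counts", seed)
  attr(out, "rejections") <- rejections
  out
}

# ---- ensembles -------------------------------------------------------------

#' Replicate a path simulator and summarize terminal values
#'
#' Runs a path simulator `replicates` times with deterministic child seeds
#' spawned from a single master seed, and summarizes the terminal per-state
#' values: mean, sample variance, and a normal-approximation 95% confidence
#' interval for the mean.  When all replicate trajectories share the same
#' time grid, the per-time mean path is retained for plotting.
#'
#' @param simulator A function called as `simulator(seed = s)` returning an
#'   `sse_trajectory`; typically a wrapper around [simulate_count_path()],
#'   [simulate_frequency_path()] or [simulate_jump_process()].
#' @param replicates Number of replicates (at least 2).
#' @param seed Master seed from which per-replicate seeds are drawn.
#' @param level Confidence level for the mean interval.
#' @return An object of class `sse_ensemble`: list with `terminal` (tibble,
#'   one row per replicate), `summary` (tibble: state, mean, variance, lower,
#'   upper), `mean_path` (tibble or `NULL`), and `replicates`.
#' @examples
#' space <- enumerate_range_states(c("A", "B"))
#' pars <- validate_params(geosse_params(
#'   w = c(A = 0.05, B = 0.05), e = c(A = 0.01, B = 0.01),
#'   d = c("A>B" = 0.02, "B>A" = 0.02), b = c("A|B" = 0.01)
#' ), space)
#' ens <- ensemble(function(seed) {
#'   simulate_count_path(pars, space, c(20, 20, 10), 2, 100, seed = seed)
#' }, replicates = 20, seed = 1)
#' ens$summary
#' @export
ensemble <- function(simulator, replicates, seed = NULL, level = 0.95) {
  if (replicates < 2) rlang::abort("`replicates` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, replicates)
  warned <- FALSE
  paths <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    paths[[r]] <- withCallingHandlers(
      simulator(seed = child_seeds[r]),
      diffsse_step_warning = function(w) {
        if (warned) invokeRestart("muffleWarning")
        warned <<- TRUE
      }
    )
  }
  term <- do.call(rbind, purrr::map(paths, terminal_values))
  labels <- colnames(term)
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- colMeans(term)
  v <- apply(term, 2, stats::var)
  se <- sqrt(v / replicates)
  summary <- tibble::tibble(
    state = labels, mean = unname(m), variance = unname(v),
    lower = unname(m - z * se), upper = unname(m + z * se)
  )
  grids <- purrr::map(paths, "time")
  mean_path <- NULL
  if (all(purrr::map_int(grids, length) == length(grids[[1]])) &&
      all(purrr::map_lgl(grids, function(g) isTRUE(all.equal(g, grids[[1]]))))) {
    acc <- Reduce(`+`, purrr::map(paths, trajectory_values)) / replicates
    mean_path <- new_trajectory(grids[[1]], acc, labels,
                                attr(paths[[1]], "kind"))
  }
  structure(
    list(
      terminal = tibble::as_tibble(as.data.frame(term)),
      summary = summary,
      mean_path = mean_path,
      replicates = replicates,
      kind = attr(paths[[1]], "kind"),
      seed = seed
    ),
    class = "sse_ensemble"
  )
}

#' @export
print.sse_ensemble <- function(x, ...) {
  cat("<sse_ensemble> ", x$replicates, " replicates, kind=", x$kind, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Realize integer initial counts from frequencies
#'
#' Figure captions state a total count and fractional initial frequencies;
#' integer counts are realized either by largest-remainder rounding (exact
#' and deterministic, the default) or by a seeded multinomial draw.
#'
#' @param total Total initial count `N(0)`.
#' @param freqs Initial frequencies (summing to 1).
#' @param space The state space.
#' @param method `"largest-remainder"` or `"multinomial"`.
#' @param seed Seed for the multinomial draw.
#' @return Named integer vector of per-state counts summing to `total`.
#' @export
initial_counts <- function(total, freqs, space,
                           method = c("largest-remainder", "multinomial"),
                           seed = NULL) {
  method <- match.arg(method)
  pi <- as_state_vector(freqs, space, "frequencies")
  if (abs(sum(pi) - 1) > 1e-9) rlang::abort("Frequencies must sum to 1.")
  if (method == "multinomial") {
    if (!is.null(seed)) set.seed(seed)
    return(stats::setNames(
      as.integer(stats::rmultinom(1, total, pi)), space$labels
    ))
  }
  raw <- total * pi
  base <- floor(raw)
  short <- round(total - sum(base))
  if (short > 0) {
    top <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  stats::setNames(as.integer(base), space$labels)
}
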