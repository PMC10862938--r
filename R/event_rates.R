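#' Per-state gain and loss event rates for a GeoSSE model
#'
#' `event_rate_components()` evaluates, for every range state, the four gain
#' components (within-region speciation `W+`, dispersal `D+`, between-region
#' speciation `B+`, local extinction from a superset `E+`) and the four loss
#' components (`W-` is identically zero; dispersal out `D-`, between-region
#' speciation of the state itself `B-`, local extinction `E-`).  All values
#' are rates (events per unit time) for the supplied count vector; divide the
#' underlying probabilities by the time step to recover them.
#'
#' `gain_rate()` and `loss_rate()` return the corresponding one-state row.
#'
#' @param counts Per-state counts: numeric vector in canonical state order
#'   (optionally named by state label) or a data frame with `state` and
#'   `count` columns.
#' @param params A validated [geosse_params()] object.
#' @param space The [enumerate_range_states()] state space.
#' @param state For the single-state accessors: a range state (character
#'   vector of regions or concatenated label).
#'
#' @return A tibble with one row per state and columns `state`, `W_plus`,
#'   `D_plus`, `B_plus`, `E_plus`, `plus_total`, `W_minus`, `D_minus`,
#'   `B_minus`, `E_minus`, `minus_total`.
#'
#' @examples
#' space <- enumerate_range_states(c("A", "B"))
#' pars <- validate_params(geosse_params(
#'   w = c(A = 0.01, B = 0.02), e = c(A = 0.169, B = 0.008),
#'   d = c("A>B" = 0.002, "B>A" = 0.178), b = c("A|B" = 0.003)
#' ), space)
#' event_rate_components(c(A = 10, B = 20, AB = 5), pars, space)
#' @export
event_rate_components <- function(counts, params, space) {
  stopifnot(inherits(space, "sse_state_space"))
  n <- as_state_vector(counts, space, "counts")
  if (any(n < 0)) rlang::abort("Counts must be nonnegative.")
  purrr::map_dfr(
    seq_along(space$states),
    function(i) state_rate_row(n, params, space, i)
  )
}

# one row of event_rate_components for state index i; counts already canonical
state_rate_row <- function(n, params, space, i) {
  regions <- space$regions
  states <- space$states
  labels <- space$labels
  s_i <- states[[i]]
  size_i <- length(s_i)

  # gains, term by term
  W_plus <- 0
  if (size_i == 1L) {
    l <- s_i
    src <- vapply(states, function(s) l %in% s, logical(1))
    W_plus <- params$w[[l]] * sum(n[src])
  }
  D_plus <- 0
  if (size_i >= 2L) {
    for (l in s_i) {
      src <- paste0(sort(setdiff(s_i, l)), collapse = "")
      ks <- setdiff(s_i, l)
      D_plus <- D_plus +
        n[[src]] * sum(vapply(ks, function(k) params$d[[dispersal_key(k, l)]], numeric(1)))
    }
  }
  B_plus <- 0
  E_plus <- 0
  for (j in seq_along(states)) {
    s_j <- states[[j]]
    if (length(s_j) > size_i && all(s_i %in% s_j)) {
      rest <- setdiff(s_j, s_i)
      B_plus <- B_plus + n[[labels[j]]] * params$b[[split_key(s_i, rest)]]
      if (length(rest) == 1L) {
        E_plus <- E_plus + n[[labels[j]]] * params$e[[rest]]
      }
    }
  }

  # losses, term by term (W- is structurally zero)
  D_minus <- 0
  if (size_i < length(regions)) {
    outside <- setdiff(regions, s_i)
    D_minus <- n[[labels[i]]] * sum(vapply(
      s_i,
      function(k) sum(vapply(outside, function(l) params$d[[dispersal_key(k, l)]], numeric(1))),
      numeric(1)
    ))
  }
  B_minus <- 0
  if (size_i >= 2L) {
    # each unordered split is met twice among proper subsets j; the half
    # corrects that double count
    subs <- unlist(purrr::map(
      seq_len(size_i - 1L),
      function(k) utils::combn(s_i, k, simplify = FALSE)
    ), recursive = FALSE)
    B_minus <- 0.5 * n[[labels[i]]] * sum(vapply(
      subs, function(j) params$b[[split_key(j, setdiff(s_i, j))]], numeric(1)
    ))
  }
  E_minus <- n[[labels[i]]] * sum(vapply(s_i, function(l) params$e[[l]], numeric(1)))

  tibble::tibble(
    state = labels[i],
    W_plus = unname(W_plus), D_plus = unname(D_plus),
    B_plus = unname(B_plus), E_plus = unname(E_plus),
    plus_total = unname(W_plus + D_plus + B_plus + E_plus),
    W_minus = 0, D_minus = unname(D_minus),
    B_minus = unname(B_minus), E_minus = unname(E_minus),
    minus_total = unname(D_minus + B_minus + E_minus)
  )
}

#' @rdname event_rate_components
#' @export
gain_rate <- function(counts, params, state, space) {
  n <- as_state_vector(counts, space, "counts")
  row <- state_rate_row(n, params, space, state_index(space, state))
  row[, c("state", "W_plus", "D_plus", "B_plus", "E_plus", "plus_total")]
}

#' @rdname event_rate_components
#' @export
loss_rate <- function(counts, params, state, space) {
  n <- as_state_vector(counts, space, "counts")
  row <- state_rate_row(n, params, space, state_index(space, state))
  row[, c("state", "W_minus", "D_minus", "B_minus", "E_minus", "minus_total")]
}

#' Per-capita gain and loss rates at given state frequencies
#'
#' Evaluates the per-lineage versions of the gain/loss rates: the same
#' component sums as [event_rate_components()] but with counts replaced by
#' frequencies.  Multiplying by the total count `N` recovers the count-scale
#' rates exactly.
#'
#' @param freqs Per-state frequencies; must be nonnegative and sum to 1
#'   (within 1e-9).
#' @inheritParams event_rate_components
#' @param state Optional single state; when supplied only that row is
#'   returned.
#'
#' @return A tibble with columns `state`, the eight components, and
#'   `p_hat_plus`, `p_hat_minus` totals.
#' @export
per_capita_rates <- function(freqs, params, space, state = NULL) {
  pi <- as_state_vector(freqs, space, "frequencies")
  if (any(pi < 0)) rlang::abort("Frequencies must be nonnegative.")
  if (abs(sum(pi) - 1) > 1e-9) {
    rlang::abort("Frequencies must sum to 1 (within 1e-9).")
  }
  idx <- if (is.null(state)) seq_along(space$states) else state_index(space, state)
  out <- purrr::map_dfr(idx, function(i) state_rate_row(pi, params, space, i))
  dplyr::rename(out, p_hat_plus = "plus_total", p_hat_minus = "minus_total")
}

#' Total rate flux in and out of a range state
#'
#' The flux of a state is the sum of incoming per-capita rate constants
#' across all adjacent source states minus the outgoing rate constants.  A
#' rate constant contributes once per source state: in two regions, the
#' within-region speciation rate of region A counts twice for state \{A\}
#' because both endemic \{A\} and widespread \{A,B\} lineages generate new
#' \{A\} endemics.
#'
#' @inheritParams event_rate_components
#' @param state Optional single state.
#' @return A tibble with columns `state` and `flux`, or a single numeric when
#'   `state` is given.
#' @export
flux_total <- function(params, space, state = NULL) {
  ones <- stats::setNames(rep(1, length(space$states)), space$labels)
  comp <- event_rate_components(ones, params, space)
  out <- tibble::tibble(
    state = comp$state,
    flux = comp$plus_total - comp$minus_total
  )
  if (!is.null(state)) {
    return(out$flux[[match(state_label(state), out$state)]])
  }
  out
}

#' BiSSE gain and loss components
#'
#' The binary-state specialization: state-dependent speciation `S+`,
#' anagenetic transitions `Q+`/`Q-`, and extinction `E-`.  Speciation never
#' removes the parent's state and extinction never adds one, so `S-` and `E+`
#' are structurally zero.
#'
#' @param counts Numeric vector of length 2: counts for states 1 and 2.
#' @param params A [bisse_params()] object.
#' @param state State index, 1 or 2.
#' @return A one-row tibble with columns `state`, `S_plus`, `E_plus`,
#'   `Q_plus`, `S_minus`, `E_minus`, `Q_minus`, `plus_total`, `minus_total`.
#' @export
bisse_components <- function(counts, params, state) {
  stopifnot(inherits(params, "bisse_params"))
  if (length(counts) != 2L || any(counts < 0)) {
    rlang::abort("`counts` must be two nonnegative numbers.")
  }
  if (!state %in% c(1L, 2L)) rlang::abort("`state` must be 1 or 2.")
  i <- as.integer(state)
  j <- 3L - i
  lam <- c(params$lambda1, params$lambda2)
  mu <- c(params$mu1, params$mu2)
  q_out <- c(params$q12, params$q21) # rate of leaving state i
  q_in <- c(params$q21, params$q12)  # rate of arriving into state i
  S_plus <- lam[i] * counts[i]
  Q_plus <- q_in[i] * counts[j]
  E_minus <- mu[i] * counts[i]
  Q_minus <- q_out[i] * counts[i]
  tibble::tibble(
    state = i,
    S_plus = S_plus, E_plus = 0, Q_plus = Q_plus,
    S_minus = 0, E_minus = E_minus, Q_minus = Q_minus,
    plus_total = S_plus + Q_plus,
    minus_total = E_minus + Q_minus
  )
}
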