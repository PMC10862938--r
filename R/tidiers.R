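#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the two-region stationary solution
#'
#' @param x An `sse_stationary2`.
#' @param ... Unused.
#' @return One row per state with its stationary frequency.
#' @export
tidy.sse_stationary2 <- function(x, ...) {
  tibble::tibble(state = names(x$pi_hat), pi_hat = unname(x$pi_hat))
}

#' @rdname tidy.sse_stationary2
#' @return `glance()`: a one-row tibble with the eigenvalues, eigenvector
#'   ratios, integration constants, and the scalar solution constants.
#' @export
glance.sse_stationary2 <- function(x, ...) {
  tibble::tibble(
    lambda1 = x$lambda1, lambda2 = x$lambda2,
    nu1 = x$nu1, nu2 = x$nu2, C1 = x$C1, C2 = x$C2,
    K_A = unname(x$K[1]), K_B = unname(x$K[2]),
    numA = x$numA, denomA = x$denomA, R = x$R, R1 = x$R1, R2 = x$R2
  )
}

#' Tidy a rate solution
#'
#' @param x An `sse_rate_solution`.
#' @param ... Unused.
#' @return One row per rate parameter (`rate`, `value`).
#' @export
tidy.sse_rate_solution <- function(x, ...) {
  tibble::tibble(rate = names(x$rates), value = unname(x$rates))
}

#' @rdname tidy.sse_rate_solution
#' @return `glance()`: feasibility and the worst stationarity residual.
#' @export
glance.sse_rate_solution <- function(x, ...) {
  tibble::tibble(
    feasible = x$feasible,
    max_abs_residual = max(abs(x$residuals$residual)),
    n_rates = length(x$rates)
  )
}

#' Tidy an ensemble summary
#'
#' @param x An `sse_ensemble`.
#' @param ... Unused.
#' @return The per-state terminal summary tibble.
#' @export
tidy.sse_ensemble <- function(x, ...) x$summary

#' @rdname tidy.sse_ensemble
#' @export
glance.sse_ensemble <- function(x, ...) {
  tibble::tibble(replicates = x$replicates, kind = x$kind)
}

#' Tidy an ensemble comparison
#'
#' @param x An `sse_comparison`.
#' @param ... Unused.
#' @return The per-state comparison tibble (already tidy).
#' @export
tidy.sse_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sse_comparison")
  out
}

#' @rdname tidy.sse_comparison
#' @export
glance.sse_comparison <- function(x, ...) {
  tibble::tibble(
    alpha = attr(x, "alpha"),
    means_indistinguishable = attr(x, "means_indistinguishable"),
    min_p_mean = min(x$p_mean),
    n_states = nrow(x)
  )
}

#' @importFrom rlang .data
NULL
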