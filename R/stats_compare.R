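#' Welch's unequal-variances t-test
#'
#' Two-sided test of equal means with the Welch-Satterthwaite degrees of
#' freedom; the workhorse for deciding whether diffusion-based and
#' jump-process ensembles share a terminal mean.
#'
#' @param sample_a,sample_b Numeric vectors (each of length at least 2).
#' @return A one-row tibble with columns `statistic`, `dof`, `p_value`.
#' @export
welch_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    rlang::abort("Both samples need at least 2 observations.")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (isTRUE(all.equal(mean(sample_a), mean(sample_b)))) {
      return(tibble::tibble(statistic = 0, dof = NA_real_, p_value = 1))
    }
    rlang::abort("Both samples are degenerate (zero variance) with different means.")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    dof = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' F-test of variance equality and the variance-ratio interval
#'
#' `f_variance_test()` computes `F = var(a) / var(b)` on
#' `(n_a - 1, n_b - 1)` degrees of freedom with the two-sided p-value
#' `2 min(P(F <= f), P(F >= f))`.  `variance_ratio_ci()` returns the ratio
#' `r = var(a) / var(b)` with the equal-tailed interval
#' `[r / q_{1 - alpha/2}, r / q_{alpha/2}]` where `q` are F quantiles.
#'
#' @inheritParams welch_test
#' @return For `f_variance_test()` a one-row tibble with `statistic`, `dof1`,
#'   `dof2`, `p_value`; for `variance_ratio_ci()` one with `ratio`, `lower`,
#'   `upper`.
#' @export
f_variance_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    rlang::abort("Both samples need at least 2 observations.")
  }
  if (stats::var(sample_b) == 0) {
    rlang::abort("Denominator sample has zero variance.")
  }
  ht <- stats::var.test(sample_a, sample_b)
  tibble::tibble(
    statistic = unname(ht$statistic),
    dof1 = unname(ht$parameter[1]),
    dof2 = unname(ht$parameter[2]),
    p_value = ht$p.value
  )
}

#' @rdname f_variance_test
#' @param level Confidence level (default 0.95).
#' @export
variance_ratio_ci <- function(sample_a, sample_b, level = 0.95) {
  if (stats::var(sample_b) == 0) {
    rlang::abort("Denominator sample has zero variance.")
  }
  ht <- stats::var.test(sample_a, sample_b, conf.level = level)
  tibble::tibble(
    ratio = unname(ht$estimate),
    lower = ht$conf.int[1],
    upper = ht$conf.int[2]
  )
}

#' Compare two simulation ensembles state by state
#'
#' The full comparison protocol between two ensembles over the same state
#' space: per-state terminal means with confidence intervals, Welch's t-test
#' of mean equality, the F-test of variance equality, and the variance ratio
#' `var(a) / var(b)` with its interval.  The overall verdict is
#' "indistinguishable means" when every Welch p-value exceeds `alpha`.
#'
#' @param a,b [ensemble()] objects (or anything with a `terminal` tibble of
#'   per-replicate terminal values over identical state columns).
#' @param alpha Significance level for the verdict (default 0.05).
#' @param level Confidence level for the intervals.
#' @return An object of class `sse_comparison`: a tibble with one row per
#'   state (means, variances, CI bounds, `p_mean`, `p_var`, `var_ratio` and
#'   its CI) carrying attributes `alpha` and `means_indistinguishable`.
#' @export
compare_ensembles <- function(a, b, alpha = 0.05, level = 0.95) {
  ta <- a$terminal
  tb <- b$terminal
  if (!identical(sort(names(ta)), sort(names(tb)))) {
    rlang::abort("The two ensembles cover different state spaces.")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- purrr::map_dfr(names(ta), function(st) {
    xa <- ta[[st]]
    xb <- tb[[st]]
    w <- welch_test(xa, xb)
    degenerate <- stats::var(xa) == 0 || stats::var(xb) == 0
    f <- if (degenerate) {
      tibble::tibble(statistic = NA_real_, p_value = NA_real_)
    } else {
      f_variance_test(xa, xb)
    }
    rci <- if (degenerate) {
      tibble::tibble(ratio = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      variance_ratio_ci(xa, xb, level)
    }
    tibble::tibble(
      state = st,
      mean_a = mean(xa), mean_b = mean(xb),
      var_a = stats::var(xa), var_b = stats::var(xb),
      lower_a = mean(xa) - z * sqrt(stats::var(xa) / length(xa)),
      upper_a = mean(xa) + z * sqrt(stats::var(xa) / length(xa)),
      lower_b = mean(xb) - z * sqrt(stats::var(xb) / length(xb)),
      upper_b = mean(xb) + z * sqrt(stats::var(xb) / length(xb)),
      p_mean = w$p_value,
      p_var = f$p_value,
      var_ratio = rci$ratio,
      var_ratio_lower = rci$lower,
      var_ratio_upper = rci$upper
    )
  })
  class(rows) <- c("sse_comparison", class(rows))
  attr(rows, "alpha") <- alpha
  attr(rows, "means_indistinguishable") <- all(rows$p_mean > alpha)
  rows
}

#' @export
print.sse_comparison <- function(x, ...) {
  cat("<sse_comparison> means ",
      if (isTRUE(attr(x, "means_indistinguishable"))) "indistinguishable"
      else "DISTINGUISHABLE",
      " at alpha = ", attr(x, "alpha"), "\n", sep = "")
  NextMethod()
}
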