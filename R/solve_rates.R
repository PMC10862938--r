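# ---- rate vector plumbing --------------------------------------------------

# canonical flat parameterization of a GeoSSE rate set for a given space
rate_names <- function(space) {
  regions <- space$regions
  d_keys <- as.vector(outer(
    regions, regions,
    function(a, b) ifelse(a == b, NA_character_, dispersal_key(a, b))
  ))
  d_keys <- d_keys[!is.na(d_keys)]
  widespread <- space$states[lengths(space$states) >= 2L]
  b_keys <- unique(unlist(purrr::map(
    widespread, function(s) purrr::map_chr(enumerate_splits(s), "key")
  )))
  c(
    paste0("w:", regions), paste0("e:", regions),
    paste0("d:", d_keys),
    if (length(b_keys) > 0) paste0("b:", b_keys)
  )
}

rates_from_vector <- function(x, space) {
  nm <- names(x)
  pick <- function(prefix) {
    sel <- startsWith(nm, prefix)
    stats::setNames(unname(x[sel]), sub(prefix, "", nm[sel], fixed = TRUE))
  }
  validate_params(
    geosse_params(w = pick("w:"), e = pick("e:"), d = pick("d:"), b = pick("b:")),
    space
  )
}

rates_to_vector <- function(params, space) {
  nms <- rate_names(space)
  vals <- vapply(nms, function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    params[[parts[1]]][[parts[2]]]
  }, numeric(1))
  stats::setNames(vals, nms)
}

# The stationarity conditions at fixed target frequencies are linear and
# homogeneous in the rate vector.  These helpers build the coefficient
# matrices by evaluating the implementation at unit rate vectors.
stationarity_coefficients <- function(target, space) {
  nms <- rate_names(space)
  drift_cols <- matrix(0, length(space$states), length(nms),
                       dimnames = list(space$labels, nms))
  flux_cols <- matrix(0, length(space$states), length(nms),
                      dimnames = list(space$labels, nms))
  for (j in seq_along(nms)) {
    unit <- stats::setNames(numeric(length(nms)), nms)
    unit[j] <- 1
    pars <- rates_from_vector(unit, space)
    pc <- per_capita_rates(target, pars, space)
    drift_cols[, j] <- pc$p_hat_plus - pc$p_hat_minus
    flux_cols[, j] <- flux_total(pars, space)$flux
  }
  list(drift = drift_cols, flux = flux_cols)
}

# ---- solver ----------------------------------------------------------------

#' Solve for GeoSSE rates compatible with target stationary frequencies
#'
#' Finds strictly positive rate parameters under which the supplied
#' frequencies are a stationary point of the deterministic frequency
#' dynamics: the per-capita gain and loss rates balance in every state, and
#' the state fluxes respect the ordering of the target frequencies (equal
#' fluxes for equal frequencies, larger flux for larger frequency).
#'
#' At fixed target frequencies both conditions are linear in the rate vector,
#' so the equalities are solved exactly by a null-space (SVD) decomposition
#' and the solver only searches the null space for a strictly positive point
#' satisfying the flux inequalities (maximin over seeded random restarts).
#' Equality residuals are therefore at machine precision whenever the system
#' is feasible.  Because the conditions are scale-free, returned rates are
#' normalized to a mean of `scale` unless some rates are held fixed.
#'
#' @param target Stationary frequencies (summing to 1, strictly positive).
#' @param space The state space.
#' @param fixed Optional named numeric of rates held at given values, using
#'   the flat names `"w:A"`, `"e:B"`, `"d:A>B"`, `"b:A|B"`.
#' @param seed Seed for the random restarts.
#' @param restarts Number of random starting points.
#' @param scale Mean rate of the normalized solution (default 0.1).
#' @param margin Enforcement margin for the strict flux inequalities.
#' @return An object of class `sse_rate_solution`: list with `params` (a
#'   validated [geosse_params()]), `residuals` (per-state stationarity
#'   residuals at the target), `flux` (per-state fluxes), `feasible`, and
#'   `target`.
#' @seealso [stationary_rate_residuals()] for the pure verifier,
#'   [rate_family_thirds()] for the closed-form two-region families.
#' @examples
#' space <- enumerate_range_states(c("A", "B"))
#' sol <- solve_rates_for_frequencies(c(1, 1, 1) / 3, space, seed = 1)
#' sol$feasible
#' attr(integrate_frequency_ode(sol$params, space, c(0.6, 0.3, 0.1),
#'                              600, 601), "terminal")
#' @export
solve_rates_for_frequencies <- function(target, space, fixed = NULL, seed = NULL,
                                        restarts = 25, scale = 0.1,
                                        margin = 1e-8) {
  target <- as_state_vector(target, space, "target frequencies")
  if (abs(sum(target) - 1) > 1e-9) rlang::abort("`target` must sum to 1.")
  if (any(target <= 0)) {
    rlang::abort("`target` frequencies must be strictly positive.")
  }
  if (!is.null(seed)) set.seed(seed)
  nms <- rate_names(space)
  co <- stationarity_coefficients(target, space)

  # equality rows: stationarity per state, plus flux ties for equal targets
  E <- co$drift
  ties <- which(outer(target, target, function(a, b) abs(a - b) < 1e-12) &
                  upper.tri(matrix(0, length(target), length(target))),
                arr.ind = TRUE)
  if (nrow(ties) > 0) {
    E <- rbind(E, co$flux[ties[, 1], , drop = FALSE] -
                 co$flux[ties[, 2], , drop = FALSE])
  }
  # strict inequality rows: flux ordering for distinct targets
  gt <- which(outer(target, target, `>`) &
                abs(outer(target, target, `-`)) >= 1e-12, arr.ind = TRUE)
  Ineq <- if (nrow(gt) > 0) {
    co$flux[gt[, 1], , drop = FALSE] - co$flux[gt[, 2], , drop = FALSE]
  } else {
    matrix(0, 0, length(nms))
  }

  free <- nms
  offset <- stats::setNames(numeric(length(nms)), nms)
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), nms)
    if (length(unknown) > 0) {
      rlang::abort(paste0("Unknown fixed rate names: ",
                          paste(unknown, collapse = ", ")))
    }
    offset[names(fixed)] <- fixed
    free <- setdiff(nms, names(fixed))
  }
  Ef <- E[, free, drop = FALSE]
  rhs <- -as.numeric(E %*% offset)

  # particular solution and null-space basis of the free equality system
  sv <- svd(Ef, nu = nrow(Ef), nv = ncol(Ef))
  tol <- max(dim(Ef)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > tol)
  part <- if (r > 0) {
    sv$v[, seq_len(r), drop = FALSE] %*%
      ((t(sv$u[, seq_len(r), drop = FALSE]) %*% rhs) / sv$d[seq_len(r)])
  } else {
    matrix(0, length(free), 1)
  }
  if (max(abs(Ef %*% part - rhs)) > 1e-10 * max(1, max(abs(rhs)))) {
    return(infeasible_solution(offset, free, part, target, space, nms))
  }
  Z <- if (r < ncol(Ef)) {
    sv$v[, (r + 1L):ncol(Ef), drop = FALSE]
  } else {
    matrix(0, ncol(Ef), 0)
  }
  if (ncol(Z) == 0) {
    return(infeasible_solution(offset, free, part, target, space, nms))
  }

  assemble <- function(x) {
    full <- offset
    full[free] <- as.numeric(part + Z %*% x)
    full
  }
  # maximize the worst slack: rate positivity and flux-ordering margins
  slack <- function(x) {
    full <- assemble(x)
    s <- full
    if (nrow(Ineq) > 0) s <- c(s, as.numeric(Ineq %*% full) - margin)
    min(s) - 1e-3 * sum(x^2) # mild shrinkage keeps the optimum bounded
  }
  best <- NULL
  for (i in seq_len(restarts)) {
    x0 <- stats::rnorm(ncol(Z))
    opt <- stats::optim(x0, slack, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 2000,
                                       reltol = 1e-12))
    if (is.null(best) || opt$value > best$value) best <- opt
    if (best$value > 0.05) break
  }
  full <- assemble(best$par)
  if (is.null(fixed) && mean(full) > 0) {
    full <- full * scale / mean(full)
  }
  finish_solution(full, target, space, margin)
}

infeasible_solution <- function(offset, free, part, target, space, nms) {
  full <- offset
  full[free] <- pmax(as.numeric(part), 0)
  finish_solution(full, target, space, 1e-8, force_infeasible = TRUE)
}

finish_solution <- function(rates, target, space, margin,
                            force_infeasible = FALSE) {
  ok_pos <- all(rates > 0)
  params <- if (ok_pos) {
    validate_params(rates_from_vector(rates, space), space, strict = TRUE)
  } else {
    rates_from_vector(pmax(rates, 0), space)
  }
  resid <- stationary_rate_residuals(params, target, space)
  flux <- flux_total(params, space)
  ord_ok <- flux_ordering_ok(flux$flux, as_state_vector(target, space), margin)
  feasible <- !force_infeasible && ok_pos && ord_ok &&
    max(abs(resid$residual)) < 1e-8
  structure(
    list(
      params = params,
      rates = rates,
      residuals = resid,
      flux = flux,
      feasible = feasible,
      target = target
    ),
    class = "sse_rate_solution"
  )
}

flux_ordering_ok <- function(flux, target, margin) {
  for (i in seq_along(target)) {
    for (j in seq_along(target)) {
      if (i >= j) next
      if (abs(target[i] - target[j]) < 1e-12) {
        if (abs(flux[i] - flux[j]) > 1e-6) return(FALSE)
      } else if (target[i] > target[j]) {
        if (flux[i] - flux[j] < margin / 2) return(FALSE)
      } else if (flux[j] - flux[i] < margin / 2) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' @export
print.sse_rate_solution <- function(x, ...) {
  cat("<sse_rate_solution> feasible=", x$feasible,
      ", max |residual| = ", signif(max(abs(x$residuals$residual)), 3), "\n",
      sep = "")
  print(x$params)
  invisible(x)
}

#' Verify rates against target stationary frequencies
#'
#' The pure verifier behind [solve_rates_for_frequencies()]: evaluates the
#' per-state stationarity residual (per-capita gain minus loss) at the target
#' frequencies for user-supplied rates.
#'
#' @param params A [geosse_params()] object.
#' @param target Frequencies at which to test stationarity.
#' @param space The state space.
#' @return A tibble with columns `state` and `residual`.
#' @export
stationary_rate_residuals <- function(params, target, space) {
  pc <- per_capita_rates(target, params, space)
  tibble::tibble(state = pc$state, residual = pc$p_hat_plus - pc$p_hat_minus)
}

#' Two-region rate families with stationary frequencies (1/3, 1/3, 1/3)
#'
#' Closed-form families of strictly positive two-region rates whose
#' stationary state frequencies are all equal to one third.  Both families
#' share the relations
#' `wA = (-2 bBA + 2 dAB + dBA - 2 eB) / 2`,
#' `wB = (-dAB + 2 eB) / 2`,
#' `eA = -bBA + dAB + dBA - eB`,
#' and differ in the admissible region of the free rates:
#' family 1 requires `0 < bBA <= dAB - eB` and `eB < dAB < 2 eB`;
#' family 2 requires `bBA > 0`, `0 < dAB <= eB` and
#' `dBA > 2 (bBA - dAB + eB)`.  Distinct members of either family give the
#' same stationary frequencies -- the many-to-one map from rates to
#' stationary pattern.
#'
#' @param family 1 or 2.
#' @param bBA,dAB,dBA,eB Free rates of the family.
#' @return A validated two-region [geosse_params()] (regions `A`, `B`).
#' @export
rate_family_thirds <- function(family, bBA, dAB, dBA, eB) {
  if (!family %in% c(1, 2)) rlang::abort("`family` must be 1 or 2.")
  if (family == 1) {
    if (!(bBA > 0 && bBA <= dAB - eB && dAB > eB && dAB < 2 * eB && dBA > 0 && eB > 0)) {
      rlang::abort("Free rates violate the family-1 region: 0 < bBA <= dAB - eB, eB < dAB < 2 eB, dBA > 0.")
    }
  } else {
    if (!(bBA > 0 && dAB > 0 && dAB <= eB && dBA > 2 * (bBA - dAB + eB) && eB > 0)) {
      rlang::abort("Free rates violate the family-2 region: bBA > 0, 0 < dAB <= eB, dBA > 2 (bBA - dAB + eB).")
    }
  }
  wA <- (-2 * bBA + 2 * dAB + dBA - 2 * eB) / 2
  wB <- (-dAB + 2 * eB) / 2
  eA <- -bBA + dAB + dBA - eB
  space <- enumerate_range_states(c("A", "B"))
  validate_params(
    geosse_params(
      w = c(A = wA, B = wB), e = c(A = eA, B = eB),
      d = c("A>B" = dAB, "B>A" = dBA), b = c("A|B" = bBA)
    ),
    space, strict = TRUE
  )
}

#' @rdname rate_family_thirds
#' @param seed Seed for the draw.
#' @details `sample_rate_family_thirds()` draws the free rates uniformly from
#'   a window inside the stated admissible region.
#' @export
sample_rate_family_thirds <- function(family, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (family == 1) {
    eB <- stats::runif(1, 0.005, 0.02)
    dAB <- stats::runif(1, 1.05 * eB, 1.95 * eB)
    bBA <- stats::runif(1, 0.2 * (dAB - eB), dAB - eB)
    dBA <- stats::runif(1, 0.05, 0.5)
  } else {
    eB <- stats::runif(1, 0.005, 0.02)
    dAB <- stats::runif(1, 0.2 * eB, eB)
    bBA <- stats::runif(1, 0.01, 0.1)
    dBA <- 2 * (bBA - dAB + eB) * stats::runif(1, 1.1, 3)
  }
  rate_family_thirds(family, bBA = bBA, dAB = dAB, dBA = dBA, eB = eB)
}
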