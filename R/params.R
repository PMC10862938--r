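#' GeoSSE rate parameters
#'
#' Container for the four GeoSSE event-rate families: per-lineage
#' within-region speciation `w`, local extinction `e`, ordered-pair dispersal
#' `d`, and between-region speciation `b` keyed by the unordered range split.
#' `b` is symmetric in the two sides of a split, so a value supplied for one
#' orientation fills both.
#'
#' @param w Named numeric: within-region speciation rate per region, e.g.
#'   `c(A = 0.01, B = 0.02)`.
#' @param e Named numeric: local-extinction (extirpation) rate per region.
#' @param d Named numeric: dispersal rates keyed `"from>to"`, e.g.
#'   `c("A>B" = 0.002, "B>A" = 0.178)`.
#' @param b Named numeric: between-region speciation rates keyed by the range
#'   split `"left|right"` (sides concatenated, order irrelevant), e.g.
#'   `c("A|B" = 0.003)` for the split of \{A,B\} into \{A\} and \{B\}.
#'
#' @return An object of class `geosse_params`.
#' @seealso [validate_params()], [enumerate_range_states()]
#' @examples
#' geosse_params(
#'   w = c(A = 0.01, B = 0.02), e = c(A = 0.169, B = 0.008),
#'   d = c("A>B" = 0.002, "B>A" = 0.178), b = c("A|B" = 0.003)
#' )
#' @export
geosse_params <- function(w, e, d = numeric(0), b = numeric(0)) {
  check_named_numeric <- function(x, nm) {
    if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
      rlang::abort(paste0("`", nm, "` must be a fully named numeric vector."))
    }
    if (any(!is.finite(x))) {
      rlang::abort(paste0("`", nm, "` must be finite."))
    }
    x
  }
  w <- check_named_numeric(w, "w")
  e <- check_named_numeric(e, "e")
  d <- check_named_numeric(d, "d")
  b <- check_named_numeric(b, "b")
  if (length(d) > 0) {
    pieces <- strsplit(names(d), ">", fixed = TRUE)
    if (any(lengths(pieces) != 2L)) {
      rlang::abort("Dispersal rates must be keyed \"from>to\".")
    }
    names(d) <- vapply(
      pieces, function(p) dispersal_key(p[1], p[2]), character(1)
    )
  }
  if (length(b) > 0) {
    pieces <- strsplit(names(b), "|", fixed = TRUE)
    if (any(lengths(pieces) != 2L)) {
      rlang::abort("Between-region speciation rates must be keyed \"left|right\".")
    }
    keys <- vapply(
      pieces, function(p) split_key(p[1], p[2]), character(1)
    )
    # symmetric closure: both orientations of a split are the same rate
    dup <- duplicated(keys)
    if (any(dup)) {
      for (k in unique(keys[dup])) {
        vals <- unique(b[keys == k])
        if (length(vals) > 1) {
          rlang::abort(
            paste0("Conflicting values for symmetric split rate \"", k, "\".")
          )
        }
      }
      b <- b[!dup]
      keys <- keys[!dup]
    }
    names(b) <- keys
  }
  structure(
    list(w = w, e = e, d = d, b = b),
    class = "geosse_params"
  )
}

#' @export
print.geosse_params <- function(x, ...) {
  fmt <- function(v) {
    if (length(v) == 0) return("(none)")
    paste0(names(v), "=", signif(v, 6), collapse = ", ")
  }
  cat("<geosse_params>\n")
  cat("  w: ", fmt(x$w), "\n", sep = "")
  cat("  e: ", fmt(x$e), "\n", sep = "")
  cat("  d: ", fmt(x$d), "\n", sep = "")
  cat("  b: ", fmt(x$b), "\n", sep = "")
  if (isTRUE(attr(x, "validated"))) {
    cat("  validated (", if (isTRUE(attr(x, "strict"))) "strict" else "permissive",
        " mode)\n", sep = "")
  }
  invisible(x)
}

#' Validate GeoSSE parameters against a state space
#'
#' Checks that every required rate is present: `w` and `e` for each region,
#' `d` for each ordered region pair, and `b` for every split of every
#' widespread range state.  In strict mode all rates must be strictly
#' positive (required by the rate-from-frequency theory); in permissive mode
#' zero rates are allowed, which is how whole event classes are switched off
#' in simulation scenarios.
#'
#' @param params A [geosse_params()] object.
#' @param space An [enumerate_range_states()] state space.
#' @param strict Logical; require all rates > 0 (default `FALSE`).
#'
#' @return The validated `geosse_params`, with attributes `validated` and
#'   `strict`.  Validation is idempotent.
#' @export
validate_params <- function(params, space, strict = FALSE) {
  stopifnot(inherits(params, "geosse_params"), inherits(space, "sse_state_space"))
  regions <- space$regions
  need_w <- regions
  need_e <- regions
  need_d <- as.vector(outer(
    regions, regions,
    function(a, b) ifelse(a == b, NA_character_, dispersal_key(a, b))
  ))
  need_d <- need_d[!is.na(need_d)]
  widespread <- space$states[lengths(space$states) >= 2L]
  need_b <- unique(unlist(purrr::map(
    widespread, function(s) purrr::map_chr(enumerate_splits(s), "key")
  )))

  check_block <- function(have, need, nm) {
    extra <- setdiff(names(have), need)
    if (length(extra) > 0) {
      rlang::abort(paste0(
        "`", nm, "` references unknown keys: ", paste(extra, collapse = ", ")
      ))
    }
    missing <- setdiff(need, names(have))
    if (length(missing) > 0) {
      rlang::abort(paste0(
        "Missing `", nm, "` rates: ", paste(missing, collapse = ", ")
      ))
    }
    have <- have[need]
    if (any(have < 0)) {
      rlang::abort(paste0("`", nm, "` rates must be nonnegative."))
    }
    if (strict && any(have == 0)) {
      rlang::abort(paste0(
        "Strict validation requires all `", nm, "` rates to be > 0."
      ))
    }
    have
  }

  out <- geosse_params(
    w = check_block(params$w, need_w, "w"),
    e = check_block(params$e, need_e, "e"),
    d = check_block(params$d, need_d, "d"),
    b = if (length(need_b) > 0) check_block(params$b, need_b, "b") else numeric(0)
  )
  attr(out, "validated") <- TRUE
  attr(out, "strict") <- strict
  out
}

#' BiSSE rate parameters
#'
#' The binary-state SSE model: state-dependent speciation rates
#' `lambda1`/`lambda2`, extinction rates `mu1`/`mu2`, and anagenetic
#' transition rates `q12` (1 to 2) and `q21` (2 to 1).  BiSSE speciation does
#' not change the trait, so there are no cladogenetic components.
#'
#' @param lambda1,lambda2 Speciation rates for states 1 and 2.
#' @param mu1,mu2 Extinction rates.
#' @param q12,q21 Anagenetic transition rates.
#' @return An object of class `bisse_params`.
#' @export
bisse_params <- function(lambda1, lambda2, mu1, mu2, q12, q21) {
  vals <- c(
    lambda1 = lambda1, lambda2 = lambda2, mu1 = mu1, mu2 = mu2,
    q12 = q12, q21 = q21
  )
  if (any(!is.finite(vals)) || any(vals < 0)) {
    rlang::abort("All BiSSE rates must be finite and nonnegative.")
  }
  structure(as.list(vals), class = "bisse_params")
}
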