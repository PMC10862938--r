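#' Enumerate the range-state space of a geographic SSE model
#'
#' Builds the state space `S` of a GeoSSE-type model: every nonempty subset of
#' the region set.  States are kept in a canonical order -- by range size, then
#' lexicographically -- so that vectors, trajectory columns, and matrices built
#' from the same region set always line up.
#'
#' @param regions Character vector of region labels, e.g. `c("A", "B")`.
#'   Labels must be unique single characters (state labels are formed by
#'   concatenation, e.g. `"AB"` for the range \{A, B\}).
#'
#' @return An object of class `sse_state_space`: a list with elements
#'   `regions` (sorted region labels), `states` (list of character vectors,
#'   one per range state), and `labels` (concatenated state labels).
#'
#' @examples
#' enumerate_range_states(c("A", "B"))
#' enumerate_range_states(c("A", "B", "C"))$labels
#' @export
enumerate_range_states <- function(regions) {
  if (length(regions) < 1) {
    rlang::abort("`regions` must contain at least one region label.")
  }
  regions <- as.character(regions)
  if (anyDuplicated(regions)) {
    rlang::abort("Region labels must be unique.")
  }
  if (any(nchar(regions) != 1L)) {
    rlang::abort(
      "Region labels must be single characters so state labels are unambiguous."
    )
  }
  regions <- sort(regions)
  states <- purrr::map(
    seq_along(regions),
    function(k) utils::combn(regions, k, simplify = FALSE)
  )
  states <- purrr::flatten(states)
  structure(
    list(
      regions = regions,
      states = states,
      labels = purrr::map_chr(states, paste0, collapse = "")
    ),
    class = "sse_state_space"
  )
}

#' @export
print.sse_state_space <- function(x, ...) {
  cat(
    "<sse_state_space> ", length(x$regions), " regions (",
    paste0(x$regions, collapse = ", "), "), ",
    length(x$states), " range states: ",
    paste0("{", x$labels, "}", collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.sse_state_space <- function(x) length(x$states)

#' Canonical label of a range state
#'
#' @param state Character vector of region labels, or an already concatenated
#'   label such as `"AB"`.
#' @return Single string: the regions sorted and concatenated.
#' @export
state_label <- function(state) {
  if (length(state) == 1L && nchar(state) > 1L) {
    state <- strsplit(state, "")[[1]]
  }
  paste0(sort(unique(state)), collapse = "")
}

#' Position of a range state in the canonical ordering
#'
#' @param space An `sse_state_space`.
#' @param state A range state (character vector of regions or concatenated
#'   label).
#' @return Integer index into `space$states`.
#' @export
state_index <- function(space, state) {
  idx <- match(state_label(state), space$labels)
  if (is.na(idx)) {
    rlang::abort(
      paste0("State {", state_label(state), "} is not in the state space.")
    )
  }
  idx
}

# regions of the state at index i, as a character vector
state_regions <- function(space, i) space$states[[i]]

#' All splits of a widespread range into two daughter ranges
#'
#' Enumerates the unordered partitions of a range into two disjoint nonempty
#' subsets that jointly cover it; these are the outcomes of between-region
#' speciation.  For \{A, B, C\} the splits are \{A\}|\{B,C\}, \{B\}|\{A,C\},
#' \{C\}|\{A,B\}.
#'
#' @param state Character vector of regions (at least two).
#' @return A list of splits; each split is a list with elements `left`,
#'   `right` (character vectors) and `key` (the canonical `"left|right"` key
#'   used in rate containers).
#' @export
enumerate_splits <- function(state) {
  state <- sort(unique(as.character(state)))
  n <- length(state)
  if (n < 2L) return(list())
  seen <- character(0)
  out <- list()
  for (k in seq_len(n - 1L)) {
    sides <- utils::combn(state, k, simplify = FALSE)
    for (s in sides) {
      key <- split_key(s, setdiff(state, s))
      if (key %in% seen) next
      seen <- c(seen, key)
      parts <- strsplit(strsplit(key, "|", fixed = TRUE)[[1]], "")
      out[[length(out) + 1L]] <- list(
        left = parts[[1]], right = parts[[2]], key = key
      )
    }
  }
  out
}

# canonical "left|right" key for an unordered split into subsets s and t
split_key <- function(s, t) {
  a <- paste0(sort(unique(as.character(s))), collapse = "")
  b <- paste0(sort(unique(as.character(t))), collapse = "")
  if (length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0) {
    rlang::abort("The two sides of a range split must be disjoint.")
  }
  paste(sort(c(a, b)), collapse = "|")
}

# canonical "from>to" key for an ordered dispersal pair
dispersal_key <- function(from, to) paste0(from, ">", to)

# coerce a counts/frequency input (named or positional vector, or a data frame
# with state/value columns) to a numeric vector in canonical state order
as_state_vector <- function(x, space, what = "counts") {
  if (is.data.frame(x)) {
    cols <- intersect(c("state", "label"), names(x))
    val <- intersect(c("count", "frequency", "value"), names(x))
    if (length(cols) == 0 || length(val) == 0) {
      rlang::abort(
        "Data-frame input needs a `state` column and a `count`/`frequency`/`value` column."
      )
    }
    x <- stats::setNames(x[[val[1]]], x[[cols[1]]])
  }
  x <- as.numeric(stats::setNames(x, names(x)))
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    labs <- vapply(names(x), state_label, character(1))
    if (!setequal(labs, space$labels) || anyDuplicated(labs)) {
      rlang::abort(
        paste0("Named ", what, " must cover every state exactly once.")
      )
    }
    x <- x[match(space$labels, labs)]
  } else if (length(x) != length(space$states)) {
    rlang::abort(
      paste0(
        "Unnamed ", what, " must have one entry per state (",
        length(space$states), ")."
      )
    )
  }
  stats::setNames(as.numeric(x), space$labels)
}
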