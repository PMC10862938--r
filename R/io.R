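# ---- model configuration files ---------------------------------------------

config_top_keys <- c("name", "note", "regions", "rates", "init", "run")

#' Read a model configuration file
#'
#' Loads a YAML or JSON model configuration and returns the validated model.
#' The schema has top-level keys `regions` (list of labels), `rates` (maps
#' `w`, `e`, `d`, `b`; dispersal keyed `"from>to"`, splits keyed
#' `"left|right"`), optional `init` (`counts`, or `total` plus
#' `frequencies`), optional `run` (`t_max`, `n_steps`, `replicates`,
#' `seed`), and optional `name`/`note`.  Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param strict Passed to [validate_params()].
#' @return A list with elements `space`, `params`, `init`, `run`, `name`,
#'   `note`.
#' @export
load_config <- function(path, strict = FALSE) {
  if (!file.exists(path)) rlang::abort(paste0("No such file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_model_config(raw, strict = strict)
}

# validate a raw configuration list (shared by load_config and fixtures)
as_model_config <- function(raw, strict = FALSE) {
  unknown <- setdiff(names(raw), config_top_keys)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown configuration keys: ",
                        paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$regions) || is.null(raw$rates)) {
    rlang::abort("A configuration needs `regions` and `rates`.")
  }
  bad_rate <- setdiff(names(raw$rates), c("w", "e", "d", "b"))
  if (length(bad_rate) > 0) {
    rlang::abort(paste0("Unknown rate blocks: ", paste(bad_rate, collapse = ", ")))
  }
  space <- enumerate_range_states(unlist(raw$regions))
  params <- validate_params(
    geosse_params(
      w = unlist(raw$rates$w), e = unlist(raw$rates$e),
      d = if (is.null(raw$rates$d)) numeric(0) else unlist(raw$rates$d),
      b = if (is.null(raw$rates$b)) numeric(0) else unlist(raw$rates$b)
    ),
    space, strict = strict
  )
  init <- NULL
  if (!is.null(raw$init)) {
    bad <- setdiff(names(raw$init), c("counts", "total", "frequencies"))
    if (length(bad) > 0) {
      rlang::abort(paste0("Unknown init keys: ", paste(bad, collapse = ", ")))
    }
    init <- raw$init
    if (!is.null(init$counts)) {
      init$counts <- as_state_vector(unlist(init$counts), space, "initial counts")
    }
    if (!is.null(init$frequencies)) {
      init$frequencies <- as_state_vector(unlist(init$frequencies), space,
                                          "initial frequencies")
    }
  }
  run <- NULL
  if (!is.null(raw$run)) {
    bad <- setdiff(names(raw$run), c("t_max", "n_steps", "n_grid",
                                     "replicates", "seed", "epsilon"))
    if (length(bad) > 0) {
      rlang::abort(paste0("Unknown run keys: ", paste(bad, collapse = ", ")))
    }
    run <- raw$run
  }
  list(
    space = space, params = params, init = init, run = run,
    name = raw$name, note = raw$note
  )
}

#' Write a model configuration file
#'
#' Inverse of [load_config()]: serializes a model (or a fixture) back to YAML
#' or JSON.  Round-trips are lossless at full double precision.
#'
#' @param config A list as returned by [load_config()] or [sse_fixture()].
#' @param path Output path; format chosen by extension (`.json` vs YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- list(
    name = config$name,
    note = config$note,
    regions = as.list(config$space$regions),
    rates = list(
      w = as.list(config$params$w), e = as.list(config$params$e),
      d = as.list(config$params$d), b = as.list(config$params$b)
    )
  )
  if (!is.null(config$init)) {
    raw$init <- purrr::map(config$init, function(x) {
      if (is.null(names(x))) as.list(x) else as.list(stats::setNames(as.numeric(x), names(x)))
    })
  }
  if (!is.null(config$run)) raw$run <- config$run
  raw <- raw[!vapply(raw, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path, precision = 15)
  }
  invisible(path)
}

# ---- trajectory and report writers -----------------------------------------

#' Write and read trajectories as TSV
#'
#' Trajectories are stored as plain TSV: a `time` column followed by one
#' column per state, named by the concatenated region labels (`A`, `B`,
#' `AB`, ...).
#'
#' @param traj An `sse_trajectory`.
#' @param path Output path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `sse_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(traj)), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @param kind Trajectory kind to restore (`"counts"` or `"frequencies"`).
#' @export
read_trajectory <- function(path, kind = c("counts", "frequencies")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "time") {
    rlang::abort("A trajectory file must start with a `time` column.")
  }
  new_trajectory(df$time, as.matrix(df[, -1, drop = FALSE]),
                 names(df)[-1], kind)
}

#' Write an analysis report as JSON
#'
#' Serializes a tibble or list of results (comparison reports, stationary
#' summaries, mixing times) to JSON at full double precision, with rounded
#' display copies alongside.
#'
#' @param report A data frame or list.
#' @param path Output path.
#' @param digits Digits for the rounded display copy (default 4).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, digits = 4) {
  payload <- list(
    values = report,
    display = if (is.data.frame(report)) {
      dplyr::mutate(report, dplyr::across(dplyr::where(is.numeric),
                                          function(x) round(x, digits)))
    } else {
      rapply(report, function(x) round(x, digits), classes = "numeric",
             how = "replace")
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
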