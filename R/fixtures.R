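# Scenario fixtures: every worked simulation and stationary-analysis
# configuration used in the documentation and the validation suite, built in
# code so they stay in one place.  Initial conditions are given as a total
# count plus frequencies where the scenario is count-based, or frequencies
# alone where it is purely deterministic.

fixture_registry <- function() {
  w3 <- function(a, b, c) c(A = a, B = b, C = c)
  d3 <- function(ab, ac, bc, ba = ab, ca = ac, cb = bc) {
    c("A>B" = ab, "A>C" = ac, "B>C" = bc, "B>A" = ba, "C>A" = ca, "C>B" = cb)
  }
  b3 <- function(ab, ac, bc, a_bc, ac_b, ab_c) {
    c("A|B" = ab, "A|C" = ac, "B|C" = bc,
      "A|BC" = a_bc, "AC|B" = ac_b, "AB|C" = ab_c)
  }
  two <- function(wA, wB, eA, eB, dAB, dBA, bBA) {
    list(
      regions = c("A", "B"),
      rates = list(w = c(A = wA, B = wB), e = c(A = eA, B = eB),
                   d = c("A>B" = dAB, "B>A" = dBA), b = c("A|B" = bBA))
    )
  }
  list(
    example1 = list(
      regions = c("A", "B", "C"),
      rates = list(
        w = w3(0.03, 0.03, 0.03), e = w3(0, 0, 0),
        d = d3(0, 0, 0),
        b = b3(0.08, 0.10, 0.06, 0.04, 0.12, 0.06)
      ),
      init = list(total = 40, frequencies = rep(1 / 7, 7)),
      run = list(t_max = 10, n_steps = 1000, replicates = 1000),
      note = "3-region scenario: within- and between-region speciation only"
    ),
    example2 = list(
      regions = c("A", "B", "C"),
      rates = list(
        w = w3(0.03, 0.03, 0.03), e = w3(0, 0, 0),
        d = d3(0.03, 0.04, 0.05),
        b = b3(0, 0, 0, 0, 0, 0)
      ),
      init = list(total = 40,
                  frequencies = c(rep(1 / 6, 6), 0)),
      run = list(t_max = 10, n_steps = 1000, replicates = 1000),
      note = "3-region scenario: within-region speciation and dispersal only"
    ),
    example3 = list(
      regions = c("A", "B", "C"),
      rates = list(
        w = w3(0.03, 0.03, 0.03), e = w3(0.01, 0.02, 0.025),
        d = d3(0, 0, 0),
        b = b3(0, 0, 0, 0, 0, 0)
      ),
      init = list(total = 40, frequencies = rep(1 / 7, 7)),
      run = list(t_max = 10, n_steps = 1000, replicates = 1000),
      note = "3-region scenario: within-region speciation and local extinction only"
    ),
    example4 = list(
      regions = c("A", "B", "C"),
      rates = list(
        w = w3(0.09, 0.06, 0.07), e = w3(0.002, 0.003, 0.001),
        d = d3(0.006, 0.003, 0.001),
        b = b3(0.04, 0.04, 0.04, 0.04, 0.04, 0.04)
      ),
      init = list(total = 40,
                  frequencies = c(0, 0, 0, rep(1 / 4, 4))),
      run = list(t_max = 10, n_steps = 1000, replicates = 1000),
      note = "3-region scenario with every event class active"
    ),
    thirds_family1_a = c(
      two(0.090, 0.0005, 0.176, 0.008, 0.015, 0.173, 0.004),
      list(
        init = list(frequencies = c(0.45, 0.45, 0.10)),
        run = list(t_max = 250, n_grid = 1000, epsilon = 1e-9),
        note = paste(
          "Family-1 equal-thirds scenario; the quoted wB of about zero is",
          "stored as the family value (-dAB + 2 eB) / 2 = 0.0005"
        )
      )
    ),
    thirds_family1_b = c(
      two(0.160, 0.002, 0.315, 0.009, 0.014, 0.310, 0.001),
      list(
        init = list(frequencies = c(0.10, 0.45, 0.45)),
        run = list(t_max = 250, n_grid = 1000, epsilon = 1e-9),
        note = "Family-1 equal-thirds scenario, second initial condition"
      )
    ),
    thirds_family2_a = c(
      two(0.107, 0.008, 0.309, 0.008, 0.001, 0.405, 0.089),
      list(
        init = list(frequencies = c(0.45, 0.45, 0.10)),
        run = list(t_max = 60, n_grid = 1000, epsilon = 1e-9),
        note = "Family-2 equal-thirds scenario"
      )
    ),
    thirds_family2_b = c(
      two(0.049, 0.005, 0.470, 0.008, 0.006, 0.843, 0.371),
      list(
        init = list(frequencies = c(0.10, 0.45, 0.45)),
        run = list(t_max = 60, n_grid = 1000, epsilon = 1e-9),
        note = "Family-2 equal-thirds scenario, second initial condition"
      )
    ),
    stationary_case1 = c(
      two(0.01, 0.02, 0.169, 0.008, 0.002, 0.178, 0.003),
      list(
        note = "First stationary-frequency comparison case"
      )
    ),
    stationary_case2 = c(
      two(0.0006, 0.0003, 0.0048, 0.0045, 0.0370, 0.03703, 0),
      list(
        note = "Second stationary-frequency comparison case (rates quoted approximately; bBA about 0)"
      )
    )
  )
}

#' Bundled scenario fixtures
#'
#' `sse_fixtures()` lists the names of the bundled worked scenarios;
#' `sse_fixture(name)` returns one as a validated model configuration (the
#' same structure as [load_config()]), including initial conditions and run
#' settings where the scenario defines them.
#'
#' @param name Fixture name, one of `sse_fixtures()`.
#' @return `sse_fixtures()`: character vector.  `sse_fixture()`: list with
#'   `space`, `params`, `init`, `run`, `name`, `note`.
#' @examples
#' sse_fixtures()
#' fx <- sse_fixture("stationary_case1")
#' fx$params
#' @export
sse_fixtures <- function() names(fixture_registry())

#' @rdname sse_fixtures
#' @export
sse_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    rlang::abort(paste0(
      "Unknown fixture \"", name, "\". Available: ",
      paste(names(reg), collapse = ", ")
    ))
  }
  raw <- reg[[name]]
  raw$name <- name
  as_model_config(raw)
}
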