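# shared builders for random and worked parameter sets

space2 <- enumerate_range_states(c("A", "B"))
space3 <- enumerate_range_states(c("A", "B", "C"))

params2 <- function(wA, wB, eA, eB, dAB, dBA, bBA, strict = FALSE) {
  validate_params(
    geosse_params(
      w = c(A = wA, B = wB), e = c(A = eA, B = eB),
      d = c("A>B" = dAB, "B>A" = dBA), b = c("A|B" = bBA)
    ),
    space2, strict = strict
  )
}

case1_params <- function() {
  params2(0.01, 0.02, 0.169, 0.008, 0.002, 0.178, 0.003)
}

# one uniformly random strictly positive parameter set on a given space
random_params <- function(space, lo = 1e-3, hi = 1) {
  nms <- diffsse:::rate_names(space)
  vals <- stats::setNames(stats::runif(length(nms), lo, hi), nms)
  diffsse:::rates_from_vector(vals, space)
}

random_counts <- function(space, max = 50) {
  stats::setNames(sample.int(max, length(space$states), replace = TRUE),
                  space$labels)
}
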