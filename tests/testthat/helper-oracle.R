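# Independent brute-force oracle for the per-state gain/loss rates: instead
# of evaluating the summation formulas, enumerate every concrete elementary
# event (who speciates/disperses/splits/goes locally extinct, and where) and
# attribute its rate to the states whose counts it raises or lowers.

oracle_components <- function(counts, params, space) {
  labels <- space$labels
  k <- length(labels)
  zero <- stats::setNames(numeric(k), labels)
  acc <- list(
    W_plus = zero, D_plus = zero, B_plus = zero, E_plus = zero,
    W_minus = zero, D_minus = zero, B_minus = zero, E_minus = zero
  )
  n <- counts
  names(n) <- labels
  for (j in seq_len(k)) {
    s_j <- space$states[[j]]
    Nj <- n[[labels[j]]]
    # within-region speciation: new endemic in region l, parent unchanged
    for (l in s_j) {
      acc$W_plus[[l]] <- acc$W_plus[[l]] + Nj * params$w[[l]]
    }
    # dispersal: j -> j + {l}, for every unoccupied l, from any occupied k
    for (l in setdiff(space$regions, s_j)) {
      rate <- Nj * sum(vapply(s_j, function(kk) params$d[[paste0(kk, ">", l)]],
                              numeric(1)))
      tgt <- paste0(sort(c(s_j, l)), collapse = "")
      acc$D_plus[[tgt]] <- acc$D_plus[[tgt]] + rate
      acc$D_minus[[labels[j]]] <- acc$D_minus[[labels[j]]] + rate
    }
    # between-region speciation: parent j replaced by the two split daughters
    if (length(s_j) >= 2) {
      for (sp in enumerate_splits(s_j)) {
        rate <- Nj * params$b[[sp$key]]
        acc$B_minus[[labels[j]]] <- acc$B_minus[[labels[j]]] + rate
        left <- paste0(sort(sp$left), collapse = "")
        right <- paste0(sort(sp$right), collapse = "")
        acc$B_plus[[left]] <- acc$B_plus[[left]] + rate
        acc$B_plus[[right]] <- acc$B_plus[[right]] + rate
      }
    }
    # local extinction: j -> j - {l} (or the species dies when endemic)
    for (l in s_j) {
      rate <- Nj * params$e[[l]]
      acc$E_minus[[labels[j]]] <- acc$E_minus[[labels[j]]] + rate
      rest <- setdiff(s_j, l)
      if (length(rest) > 0) {
        tgt <- paste0(sort(rest), collapse = "")
        acc$E_plus[[tgt]] <- acc$E_plus[[tgt]] + rate
      }
    }
  }
  tibble::tibble(
    state = labels,
    W_plus = unname(acc$W_plus), D_plus = unname(acc$D_plus),
    B_plus = unname(acc$B_plus), E_plus = unname(acc$E_plus),
    plus_total = unname(acc$W_plus + acc$D_plus + acc$B_plus + acc$E_plus),
    W_minus = 0, D_minus = unname(acc$D_minus),
    B_minus = unname(acc$B_minus), E_minus = unname(acc$E_minus),
    minus_total = unname(acc$D_minus + acc$B_minus + acc$E_minus)
  )
}
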