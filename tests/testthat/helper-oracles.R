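# Independent brute-force oracles used across test files. These stay
# deliberately naive (double loops over all residue/atom pairs) so they
# check the vectorised implementations against first principles.

# All residue pairs whose minimum atom-atom distance is <= cutoff, by
# exhaustive enumeration.
brute_force_contacts <- function(structure, cutoff = 6,
                                 min_separation = 3, model = 1) {
  a <- structure[structure$model == model, , drop = FALSE]
  L <- max(a$residue)
  out <- NULL
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (j - i < min_separation) next
      ai <- a[a$residue == i, c("x", "y", "z")]
      aj <- a[a$residue == j, c("x", "y", "z")]
      dmin <- Inf
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- sqrt(sum((as.numeric(ai[p, ]) - as.numeric(aj[q, ]))^2))
          dmin <- min(dmin, d)
        }
      }
      if (dmin <= cutoff) out <- rbind(out, c(i, j, dmin))
    }
  }
  if (is.null(out)) {
    return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  }
  tibble::tibble(i = as.integer(out[, 1]), j = as.integer(out[, 2]),
                 dist = out[, 3])
}

# A tiny extended bead chain as a structure tibble.
bead_chain <- function(n, spacing = 3.8) {
  as_structure(cbind(spacing * (seq_len(n) - 1), 0, 0), id = "chain")
}

# Random contact subsets for metric-kernel checks.
random_pairs <- function(L, n_pairs) {
  pairs <- t(replicate(n_pairs, sort(sample.int(L, 2))))
  tibble::tibble(i = pairs[, 1], j = pairs[, 2])
}
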