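#' @title Property-ranked residue elimination
#' @description Residues are ranked by hydrophobicity, connectivity or
#' their product (both scaled to \[0, 1\]); the lowest-ranked residues are
#' removed first, contacts touching a removed residue are dropped (the
#' chain length L in the TCD denominator is kept fixed, so removal acts on
#' the contact subset only), and the TCD / ln k_f correlation is
#' recomputed as the removal percentage grows. Significance comes from
#' percentile envelopes over uniformly random removals of the same counts.
#' @name core_elimination
NULL

#' Rank residues and remove the lowest percentage
#'
#' Removes `floor(percent * L / 100)` lowest-valued residues. When
#' several residues tie at the removal boundary, `tie_reps` independent
#' uniform draws of the boundary set are returned; with all values
#' distinct the single deterministic removal is returned.
#'
#' @param values Numeric vector of per-residue ranking values (low =
#'   removed first).
#' @param percent Percentage to remove, in `[0, 100)`.
#' @param tie_reps Number of random tie resolutions (default 1000).
#' @param seed Optional RNG seed.
#' @return List of integer vectors of retained residue indices (length 1
#'   when the removal is deterministic).
#' @export
rank_and_remove <- function(values, percent, tie_reps = 1000, seed = NULL) {
  L <- length(values)
  stop_unless(percent >= 0 && percent < 100,
              "percent must be in [0, 100)")
  n_rm <- floor(percent * L / 100)
  stop_unless(n_rm < L, "removal would eliminate every residue")
  if (n_rm == 0) return(list(seq_len(L)))
  v_sorted <- sort(values)
  v_cut <- v_sorted[n_rm]
  below <- which(values < v_cut)
  pool <- which(values == v_cut)
  need <- n_rm - length(below)
  if (need == 0 || need == length(pool)) {
    removed <- c(below, pool[seq_len(need)])
    return(list(setdiff(seq_len(L), removed)))
  }
  with_seed_if(seed, purrr::map(seq_len(tie_reps), function(t) {
    removed <- c(below, sample(pool, need))
    setdiff(seq_len(L), removed)
  }))
}

# TCD over the contacts whose endpoints are both retained; NA when no
# contact survives.
tcd_retained <- function(contacts, retained, L) {
  member <- logical(L)
  member[retained] <- TRUE
  keep <- member[contacts$i] & member[contacts$j]
  if (!any(keep)) return(NA_real_)
  sum(contacts$sep[keep]) / L^2
}

# r^2 of ln_kf against per-protein values; NA when degenerate.
cohort_r2 <- function(vals, ln_kf) {
  ok <- !is.na(vals)
  if (sum(ok) < 3 || var(vals[ok]) == 0) return(NA_real_)
  cor(vals[ok], ln_kf[ok])^2
}

#' Elimination curve with random-removal envelopes
#'
#' At each grid percentage, computes the mean TCD / ln k_f r^2 over
#' tie-resolution replicates for the property ranking, together with the
#' 1/5/50/95/99 percentile envelope of r^2 over `rand_reps` uniformly
#' random removals of the same per-protein counts. Each grid point draws
#' from a sub-stream derived from `seed`, so single points are
#' reproducible in isolation.
#'
#' @param cohort Cohort tibble from [build_cohort()] (needs `contacts` and
#'   `properties` list-columns).
#' @param rates Tibble with `protein_id`, `ln_kf`.
#' @param property `"hydrophobicity"`, `"connectivity"` or `"product"`
#'   (scaled connectivity x scaled hydrophobicity).
#' @param grid Percentages (default `seq(0, 80, by = 1)`).
#' @param tie_reps Tie-resolution replicates (default 100).
#' @param rand_reps Random-removal replicates per grid point (default
#'   1000).
#' @param seed Base RNG seed.
#' @return Tibble of class `ln_elim` with columns `property`, `percent`,
#'   `mean_r2`, `p1`, `p5`, `p50`, `p95`, `p99`.
#' @export
elimination_curve <- function(cohort, rates,
                              property = c("hydrophobicity", "connectivity",
                                           "product"),
                              grid = seq(0, 80, by = 1), tie_reps = 100,
                              rand_reps = 1000, seed = 1) {
  property <- match.arg(property)
  stop_unless(!is.unsorted(grid), "grid must be sorted")
  ln_kf <- rates$ln_kf[match(cohort$protein_id, rates$protein_id)]
  stop_unless(!anyNA(ln_kf), "rates missing for some cohort proteins")
  vals_of <- function(pr) switch(property,
    hydrophobicity = pr$hydrophobicity,
    connectivity = as.numeric(pr$connectivity),
    product = pr$connectivity_scaled * pr$hydrophobicity_scaled)
  prop_vals <- purrr::map(cohort$properties, vals_of)

  rows <- purrr::imap(grid, function(pct, gi) {
    with_seed_if(derive_seed(seed, gi), {
      retained <- purrr::map2(prop_vals, cohort$L, function(v, L)
        rank_and_remove(v, pct, tie_reps))
      n_samp <- max(purrr::map_int(retained, length))
      prop_r2 <- mean(vapply(seq_len(n_samp), function(t) {
        vals <- vapply(seq_len(nrow(cohort)), function(p) {
          sets <- retained[[p]]
          tcd_retained(cohort$contacts[[p]],
                       sets[[(t - 1) %% length(sets) + 1]], cohort$L[p])
        }, numeric(1))
        cohort_r2(vals, ln_kf)
      }, numeric(1)), na.rm = TRUE)

      n_rm <- floor(pct * cohort$L / 100)
      rand_r2 <- vapply(seq_len(rand_reps), function(rep) {
        vals <- vapply(seq_len(nrow(cohort)), function(p) {
          keep <- if (n_rm[p] == 0) seq_len(cohort$L[p]) else
            sample.int(cohort$L[p], cohort$L[p] - n_rm[p])
          tcd_retained(cohort$contacts[[p]], keep, cohort$L[p])
        }, numeric(1))
        cohort_r2(vals, ln_kf)
      }, numeric(1))
      qs <- quantile(rand_r2, c(0.01, 0.05, 0.50, 0.95, 0.99),
                     na.rm = TRUE, names = FALSE)
      tibble::tibble(property = property, percent = pct, mean_r2 = prop_r2,
                     p1 = qs[1], p5 = qs[2], p50 = qs[3], p95 = qs[4],
                     p99 = qs[5])
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ln_elim", class(out))
  out
}
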