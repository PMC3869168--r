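#' @title Closed loops and locks
#' @description A closed loop is a chain segment of 12-50 residues whose
#' two ends approach within 6 Angstrom (heavy-atom minimum distance). The
#' residues clustered at the two ends that hold the loop shut are its lock
#' regions; a minimal pair (one residue per end) represents the lock in
#' restricted-metric calculations, and the minimal pairs plus every residue
#' contacting them form the locks-plus-neighbours core.
#' @name closed_loops
NULL

# Min heavy-atom distance between each residue of set1 and each of set2
# (matrix |set1| x |set2|) for one model.
residue_pair_dists <- function(structure, set1, set2, model = 1) {
  a <- model_atoms(structure, model)
  a1 <- a[a$residue %in% set1, , drop = FALSE]
  a2 <- a[a$residue %in% set2, , drop = FALSE]
  m <- matrix(Inf, length(set1), length(set2),
              dimnames = list(set1, set2))
  if (nrow(a1) == 0 || nrow(a2) == 0) return(m)
  dx <- outer(a1$x, a2$x, "-"); dy <- outer(a1$y, a2$y, "-")
  dz <- outer(a1$z, a2$z, "-")
  D <- sqrt(dx^2 + dy^2 + dz^2)
  for (p in seq_along(set1)) for (q in seq_along(set2)) {
    sel <- a1$residue == set1[p]
    sel2 <- a2$residue == set2[q]
    m[p, q] <- min(D[sel, sel2])
  }
  m
}

#' Enumerate closed-loop candidates
#'
#' One candidate per contact pair whose inclusive length
#' (`end - start + 1`) falls within `[min_len, max_len]`.
#'
#' @param contacts Contact tibble from [compute_contacts()] (6 Angstrom
#'   cutoff for the standard criterion).
#' @param min_len,max_len Inclusive loop-length bounds (defaults 12 and 50).
#' @return Tibble with columns `start`, `end`, `length`.
#' @export
enumerate_closed_loops <- function(contacts, min_len = 12, max_len = 50) {
  len <- contacts$j - contacts$i + 1
  keep <- len >= min_len & len <= max_len
  tibble::tibble(start = contacts$i[keep], end = contacts$j[keep],
                 length = len[keep]) |>
    dplyr::arrange(.data$start, .data$end)
}

# Lock-region growth rule: around each loop end, take the maximal
# contiguous run (offsets within +/-3, so at most 7 residues) of residues
# that contact the opposite end's +/-2 window within `cutoff`; the end
# itself is always a member, and a region is padded to two residues with
# the closest flanking neighbour if growth leaves it alone.
grow_lock_region <- function(structure, this_end, other_end, L, cutoff = 6) {
  cand <- (this_end - 3):(this_end + 3)
  cand <- cand[cand >= 1 & cand <= L]
  oppo <- (other_end - 2):(other_end + 2)
  oppo <- oppo[oppo >= 1 & oppo <= L]
  d <- residue_pair_dists(structure, cand, oppo)
  hit <- apply(d, 1, min) <= cutoff
  hit[cand == this_end] <- TRUE
  k <- which(cand == this_end)
  lo <- k; while (lo > 1 && hit[lo - 1]) lo <- lo - 1
  hi <- k; while (hi < length(cand) && hit[hi + 1]) hi <- hi + 1
  region <- cand[lo:hi]
  if (length(region) < 2) {
    flank <- setdiff(c(this_end - 1, this_end + 1), region)
    flank <- flank[flank >= 1 & flank <= L]
    if (length(flank) > 0) {
      df <- residue_pair_dists(structure, flank, oppo)
      region <- sort(c(region, flank[which.min(apply(df, 1, min))]))
    }
  }
  sort(region)
}

#' Attach lock regions to loop candidates
#'
#' @param loops Tibble from [enumerate_closed_loops()].
#' @param structure Structure tibble (model 1 geometry used).
#' @param cutoff Heavy-atom contact cutoff in Angstrom (default 6).
#' @return `loops` with list-columns `lock_start` and `lock_end` (integer
#'   residue sets, 2-7 residues each).
#' @export
lock_regions <- function(loops, structure, cutoff = 6) {
  L <- structure_length(structure)
  loops$lock_start <- purrr::map2(loops$start, loops$end, function(s, e)
    grow_lock_region(structure, s, e, L, cutoff))
  loops$lock_end <- purrr::map2(loops$start, loops$end, function(s, e)
    grow_lock_region(structure, e, s, L, cutoff))
  loops
}

#' Score loop candidates by their end-region properties
#'
#' Each loop end is scored as the product of window-averaged scaled
#' connectivity, scaled hydrophobicity and conservation (windows centered
#' on the end residue, truncated at the chain termini); the lock score is
#' the mean of the two end scores. With uniform hydrophobicity and
#' conservation the ranking therefore reduces to connectivity alone.
#'
#' @param loops Tibble with `start` and `end` columns.
#' @param properties Per-residue tibble from [residue_properties()].
#' @param window Window width, one of 1, 3, 5.
#' @return `loops` with a `score` column.
#' @export
score_lock_region <- function(loops, properties, window = 1) {
  stop_unless(window %in% c(1, 3, 5), "window must be 1, 3 or 5")
  L <- nrow(properties)
  stop_unless(max(c(loops$start, loops$end, 0)) <= L,
              "properties do not cover all loop ends")
  h <- (window - 1) / 2
  end_score <- function(r) {
    idx <- max(1, r - h):min(L, r + h)
    mean(properties$connectivity_scaled[idx]) *
      mean(properties$hydrophobicity_scaled[idx]) *
      mean(properties$conservation[idx])
  }
  loops$score <- vapply(seq_len(nrow(loops)), function(k)
    mean(c(end_score(loops$start[k]), end_score(loops$end[k]))), numeric(1))
  loops
}

#' Greedy non-overlapping loop selection
#'
#' Candidates are taken in order of descending score (ties broken by
#' shorter length, then smaller start). A candidate is accepted when its
#' interior (`start+1 .. end-1`) overlaps the interior of every previously
#' accepted loop by at most `max_overlap` residues; shared lock endpoints
#' are always permitted because endpoints are not part of the interior.
#' Candidates with `score <= min_score` are discarded, so loops whose ends
#' carry no property weight at all are never selected.
#'
#' @param candidates Scored tibble from [score_lock_region()] (a missing
#'   `score` column is treated as all-equal scores).
#' @param max_overlap Maximum interior overlap in residues (default 5).
#' @param min_score Exclusive lower bound on score (default 0).
#' @return The accepted subset, in acceptance order, with a `loop` index
#'   column.
#' @export
select_loops <- function(candidates, max_overlap = 5, min_score = 0) {
  if (is.null(candidates$score)) candidates$score <- 1
  cand <- candidates[candidates$score > min_score, , drop = FALSE]
  if (nrow(cand) == 0) return(dplyr::mutate(cand, loop = integer(0)))
  ord <- order(-cand$score, cand$length, cand$start)
  cand <- cand[ord, , drop = FALSE]
  accepted <- integer(0)
  interiors <- list()
  for (k in seq_len(nrow(cand))) {
    interior <- if (cand$end[k] - cand$start[k] >= 2)
      (cand$start[k] + 1):(cand$end[k] - 1) else integer(0)
    ok <- all(vapply(interiors, function(acc)
      length(intersect(interior, acc)) <= max_overlap, logical(1)))
    if (ok) {
      accepted <- c(accepted, k)
      interiors[[length(interiors) + 1]] <- interior
    }
  }
  out <- cand[accepted, , drop = FALSE]
  out$loop <- seq_len(nrow(out))
  dplyr::relocate(out, "loop")
}

#' Refine lock regions against an NMR ensemble
#'
#' A lock residue is retained when it contacts the opposite lock region
#' (minimum heavy-atom distance within `cutoff`) in at least
#' `persistence_threshold` of the ensemble models. Loops whose refined
#' lock falls below two residues in total, or loses one side entirely, are
#' flagged in `lock_flagged`.
#'
#' @param loops Tibble with `lock_start`/`lock_end` list-columns.
#' @param ensemble Multi-model structure tibble (at least 2 models).
#' @param persistence_threshold Minimum fraction of models (default 0.5).
#' @param cutoff Heavy-atom cutoff in Angstrom (default 6).
#' @return `loops` with list-columns `lock_start_refined`,
#'   `lock_end_refined`, `persistence_start`, `persistence_end` and a
#'   logical `lock_flagged`.
#' @export
refine_locks_nmr <- function(loops, ensemble, persistence_threshold = 0.5,
                             cutoff = 6) {
  M <- n_models(ensemble)
  stop_unless(M >= 2,
    "ensemble has a single model; NMR refinement needs >= 2 models (use the unrefined locks instead)")
  persist_frac <- function(region, opposite) {
    hits <- vapply(sort(unique(ensemble$model)), function(m) {
      d <- residue_pair_dists(ensemble, region, opposite, model = m)
      apply(d, 1, min) <= cutoff
    }, logical(length(region)))
    if (length(region) == 1) hits <- matrix(hits, nrow = 1)
    rowMeans(hits)
  }
  res <- purrr::map(seq_len(nrow(loops)), function(k) {
    a <- loops$lock_start[[k]]; b <- loops$lock_end[[k]]
    fa <- persist_frac(a, b); fb <- persist_frac(b, a)
    list(a = a[fa >= persistence_threshold],
         b = b[fb >= persistence_threshold], fa = fa, fb = fb)
  })
  loops$lock_start_refined <- purrr::map(res, "a")
  loops$lock_end_refined <- purrr::map(res, "b")
  loops$persistence_start <- purrr::map(res, "fa")
  loops$persistence_end <- purrr::map(res, "fb")
  loops$lock_flagged <- purrr::map_lgl(res, function(r)
    length(r$a) == 0 || length(r$b) == 0 ||
      (length(r$a) + length(r$b)) < 2)
  loops
}

#' Reduce each lock to its minimal residue pair
#'
#' Among cross-end residue pairs in heavy-atom contact, selects the pair
#' with the largest summed connectivity; ties are broken by the smallest
#' minimum heavy-atom distance, then by lowest residue indices. Refined
#' lock regions are used when present and non-empty on both sides.
#'
#' @param loops Tibble with lock-region list-columns.
#' @param structure Structure tibble (model 1 geometry).
#' @param connectivity Integer vector of per-residue connectivities, or a
#'   tibble with `residue` and `connectivity` columns.
#' @param cutoff Heavy-atom contact cutoff in Angstrom (default 6).
#' @return `loops` with columns `pair_start`, `pair_end`, `pair_dist`.
#' @export
minimal_lock_pair <- function(loops, structure, connectivity, cutoff = 6) {
  if (is.data.frame(connectivity)) {
    conn <- connectivity$connectivity[order(connectivity$residue)]
  } else conn <- connectivity
  pick <- function(a, b) {
    d <- residue_pair_dists(structure, a, b)
    grid <- expand.grid(p = seq_along(a), q = seq_along(b))
    grid$dist <- d[cbind(grid$p, grid$q)]
    grid <- grid[grid$dist <= cutoff, , drop = FALSE]
    stop_unless(nrow(grid) > 0,
                "no cross-end contact between lock regions (%s | %s): lock invalid",
                paste(a, collapse = ","), paste(b, collapse = ","))
    grid$ra <- a[grid$p]; grid$rb <- b[grid$q]
    grid$csum <- conn[grid$ra] + conn[grid$rb]
    grid <- grid[order(-grid$csum, grid$dist, grid$ra, grid$rb), ]
    grid[1, c("ra", "rb", "dist")]
  }
  refined <- all(c("lock_start_refined", "lock_end_refined") %in%
                   names(loops))
  sel <- purrr::map(seq_len(nrow(loops)), function(k) {
    a <- loops$lock_start[[k]]; b <- loops$lock_end[[k]]
    if (refined) {
      ar <- loops$lock_start_refined[[k]]
      br <- loops$lock_end_refined[[k]]
      if (length(ar) > 0 && length(br) > 0) { a <- ar; b <- br }
    }
    pick(a, b)
  })
  loops$pair_start <- purrr::map_int(sel, ~ as.integer(.x$ra))
  loops$pair_end <- purrr::map_int(sel, ~ as.integer(.x$rb))
  loops$pair_dist <- purrr::map_dbl(sel, "dist")
  loops
}

#' Build the locks-plus-neighbours core
#'
#' The core contact set is every contact with at least one endpoint in a
#' minimal lock pair; the core residues are the minimal-pair residues plus
#' all endpoints of those contacts.
#'
#' @param minimal_pairs Integer vector of minimal-pair residues (e.g. the
#'   union of `pair_start` and `pair_end` over selected loops).
#' @param contacts Contact tibble at metric settings
#'   (`min_separation = 3`).
#' @return An object of class `ln_core`: list with `minimal_pairs`,
#'   `residues` (sorted integer vector), `contacts` (tibble subset) and
#'   the originating `id` and `L`.
#' @export
build_core <- function(minimal_pairs, contacts) {
  minimal_pairs <- sort(unique(as.integer(minimal_pairs)))
  stop_unless(length(minimal_pairs) > 0, "minimal pair set is empty")
  inside <- contacts$i %in% minimal_pairs | contacts$j %in% minimal_pairs
  core_contacts <- contacts[inside, , drop = FALSE]
  structure(list(
    id = attr(contacts, "id"),
    L = attr(contacts, "L"),
    minimal_pairs = minimal_pairs,
    residues = sort(unique(c(minimal_pairs, core_contacts$i,
                             core_contacts$j))),
    contacts = tibble::as_tibble(core_contacts)
  ), class = "ln_core")
}

#' @export
print.ln_core <- function(x, ...) {
  cat(sprintf(
    "<locks-plus-neighbours core> %s: %d core residues (of L=%s), %d core contacts, %d minimal-pair residues\n",
    x$id %||% "?", length(x$residues), x$L %||% "?", nrow(x$contacts),
    length(x$minimal_pairs)))
  invisible(x)
}

#' Find closed loops end-to-end
#'
#' Convenience pipeline: contact map, candidate enumeration, lock-region
#' growth, property scoring, greedy selection, optional NMR refinement,
#' and minimal-pair reduction.
#'
#' @param structure Structure tibble.
#' @param cutoff Heavy-atom cutoff in Angstrom (default 6).
#' @param min_len,max_len Loop-length bounds (defaults 12, 50).
#' @param window Scoring window (1, 3 or 5).
#' @param max_overlap Maximum interior overlap between selected loops.
#' @param min_score Exclusive score cutoff for selection (default 0).
#' @param conservation Optional per-residue conservation in \[0, 1\].
#' @param ensemble Optional multi-model structure for NMR refinement.
#' @param persistence_threshold Persistence fraction for refinement.
#' @return Selected loops tibble with lock regions, scores and minimal
#'   pairs; attribute `contacts` holds the metric contact map
#'   (`min_separation = 3`).
#' @export
find_loops <- function(structure, cutoff = 6, min_len = 12, max_len = 50,
                       window = 1, max_overlap = 5, min_score = 0,
                       conservation = NULL, ensemble = NULL,
                       persistence_threshold = 0.5) {
  props <- residue_properties(structure, cutoff = cutoff,
                              conservation = conservation)
  cm_loop <- compute_contacts(structure, cutoff, min_separation = min_len - 1)
  cands <- enumerate_closed_loops(cm_loop, min_len, max_len)
  cands <- lock_regions(cands, structure, cutoff)
  cands <- score_lock_region(cands, props, window)
  sel <- select_loops(cands, max_overlap, min_score)
  if (!is.null(ensemble) && nrow(sel) > 0) {
    sel <- refine_locks_nmr(sel, ensemble, persistence_threshold, cutoff)
  }
  if (nrow(sel) > 0) {
    sel <- minimal_lock_pair(sel, structure, residue_connectivity(
      structure, cutoff), cutoff)
  }
  attr(sel, "contacts") <- compute_contacts(structure, cutoff,
                                            min_separation = 3)
  attr(sel, "id") <- structure_id(structure)
  sel
}
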