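#' @title Residue contact maps
#' @description A contact map is a tibble of residue pairs `i < j` whose
#' minimum heavy-atom distance is below a cutoff, with columns `i`, `j`,
#' `sep` (`j - i`) and `dist` (the minimum heavy-atom distance, Angstrom).
#' Attributes record the protein id, chain length `L`, `cutoff` and
#' `min_separation`.
#' @name ln_contacts
NULL

new_contacts <- function(df, id, L, cutoff, min_separation) {
  df <- tibble::as_tibble(df)
  attr(df, "id") <- id
  attr(df, "L") <- L
  attr(df, "cutoff") <- cutoff
  attr(df, "min_separation") <- min_separation
  class(df) <- c("ln_contacts", class(tibble::tibble()))
  df
}

contacts_L <- function(contacts, L = NULL) {
  L %||% attr(contacts, "L") %||%
    abort("chain length L is neither supplied nor attached to the contact table")
}

# Min inter-residue heavy-atom distance pairs for one model.
# Returns tibble(i, j, dist) for pairs with dist <= cutoff and j - i >= min_sep.
model_contact_pairs <- function(atoms, cutoff, min_sep) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  res <- atoms$residue
  D <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) return(tibble::tibble(i = integer(), j = integer(),
                                            dist = numeric()))
  ri <- res[idx[, 1]]; rj <- res[idx[, 2]]
  swap <- ri > rj
  tmp <- ri[swap]; ri[swap] <- rj[swap]; rj[swap] <- tmp
  ok <- (rj - ri) >= min_sep
  if (!any(ok)) return(tibble::tibble(i = integer(), j = integer(),
                                      dist = numeric()))
  tibble::tibble(i = ri[ok], j = rj[ok], dist = D[idx][ok]) |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(dist = min(.data$dist), .groups = "drop")
}

#' Compute a residue contact map
#'
#' A pair (i, j) is in contact when the minimum distance over all
#' heavy-atom pairs is at most `cutoff` and the sequence separation
#' `j - i` is at least `min_separation`. For multi-model structures the
#' `model_policy` decides how models combine: `"first"` uses model 1,
#' `"all_models_any"` keeps pairs in contact in at least one model
#' (distance = minimum over models), `"all_models_all"` keeps pairs in
#' contact in every model (distance = the largest per-model minimum, so
#' the cutoff invariant still holds).
#'
#' @param structure Structure tibble.
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @param min_separation Minimum `j - i` (default 3, which excludes 1,2 and
#'   1,3 contacts).
#' @param model_policy One of `"first"`, `"all_models_any"`,
#'   `"all_models_all"`.
#' @return A contact tibble (see [ln_contacts]).
#' @export
#' @examples
#' s <- make_loop_protein(50, loops = data.frame(start = 10, end = 35,
#'                                               gap = 5), seed = 1)
#' compute_contacts(s)
compute_contacts <- function(structure, cutoff = 6, min_separation = 3,
                             model_policy = c("first", "all_models_any",
                                              "all_models_all")) {
  model_policy <- match.arg(model_policy)
  stop_unless(cutoff > 0, "cutoff must be positive")
  stop_unless(min_separation >= 1, "min_separation must be >= 1")
  stop_unless(nrow(structure) > 0, "empty structure")
  models <- sort(unique(structure$model))
  if (model_policy == "first") models <- models[1]
  per_model <- purrr::map(models, function(m)
    model_contact_pairs(model_atoms(structure, m), cutoff, min_separation))
  pooled <- dplyr::bind_rows(per_model)
  if (nrow(pooled) == 0) {
    return(new_contacts(
      tibble::tibble(i = integer(), j = integer(), sep = integer(),
                     dist = numeric()),
      id = structure_id(structure), L = structure_length(structure),
      cutoff = cutoff, min_separation = min_separation))
  }
  pooled <- pooled |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(n_models_hit = dplyr::n(),
                     dmin = min(.data$dist), dmax = max(.data$dist),
                     .groups = "drop")
  if (model_policy == "all_models_all") {
    pooled <- dplyr::filter(pooled, .data$n_models_hit == length(models))
    pooled$dist <- pooled$dmax
  } else {
    pooled$dist <- pooled$dmin
  }
  out <- pooled |>
    dplyr::transmute(i = .data$i, j = .data$j, sep = .data$j - .data$i,
                     dist = .data$dist) |>
    dplyr::arrange(.data$i, .data$j)
  new_contacts(out, id = structure_id(structure),
               L = structure_length(structure),
               cutoff = cutoff, min_separation = min_separation)
}

#' Per-residue connectivity
#'
#' The connectivity of a residue is the number of other residues at chain
#' distance at least `min_separation` whose minimum heavy-atom distance is
#' within `cutoff`. Both partners of a contact are counted, so the column
#' sums to twice the number of contacts.
#'
#' @inheritParams compute_contacts
#' @param min_separation Minimum `|i - j|` (default 2 for connectivity).
#' @param model Model used (default 1).
#' @return Tibble with columns `residue`, `connectivity`,
#'   `connectivity_scaled` (min-max scaled to \[0, 1\] within the protein;
#'   all-equal connectivities scale to 1).
#' @export
residue_connectivity <- function(structure, cutoff = 6, min_separation = 2,
                                 model = 1) {
  cm <- model_contact_pairs(model_atoms(structure, model), cutoff,
                            min_separation)
  L <- structure_length(structure)
  counts <- tabulate(c(cm$i, cm$j), nbins = L)
  rng <- range(counts)
  # all-equal counts: every residue is "the highest", scale to 1
  scaled <- if (diff(rng) == 0) rep(1, L) else (counts - rng[1]) / diff(rng)
  tibble::tibble(residue = seq_len(L), connectivity = counts,
                 connectivity_scaled = scaled)
}

#' Per-residue property table
#'
#' Convenience wrapper joining hydrophobicity (octanol-water scale by
#' default), connectivity and an optional conservation column into one
#' tibble, the input expected by the lock-scoring and elimination
#' functions. Conservation defaults to the constant 1 when not supplied.
#'
#' @inheritParams compute_contacts
#' @param scale Hydrophobicity scale (see [residue_hydrophobicity()]).
#' @param window Odd smoothing window for hydrophobicity (default 1).
#' @param conservation Optional numeric vector in \[0, 1\], length L.
#' @param connectivity_min_separation Minimum `|i - j|` for the
#'   connectivity count (default 2).
#' @return Tibble with columns `residue`, `resname`, `hydrophobicity`,
#'   `hydrophobicity_scaled`, `connectivity`, `connectivity_scaled`,
#'   `conservation`.
#' @export
residue_properties <- function(structure, cutoff = 6, scale = "octanol",
                               window = 1, conservation = NULL,
                               connectivity_min_separation = 2) {
  hyd <- residue_hydrophobicity(structure_resnames(structure), scale, window)
  con <- residue_connectivity(structure, cutoff,
                              connectivity_min_separation)
  L <- structure_length(structure)
  if (is.null(conservation)) conservation <- rep(1, L)
  stop_unless(length(conservation) == L && all(conservation >= 0) &&
                all(conservation <= 1),
              "conservation must be length L with values in [0, 1]")
  dplyr::left_join(hyd, con, by = "residue") |>
    dplyr::mutate(conservation = conservation)
}
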