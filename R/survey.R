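#' Chain-return lengths of a structure
#'
#' Every contact pair defines a chain return of inclusive length
#' `j - i + 1`; unlike the closed-loop finder there is no upper length
#' cap. Lengths below `min_length` are not reported (very short returns
#' are not meaningful loops).
#'
#' @param structure Structure tibble.
#' @param cutoff Heavy-atom cutoff in Angstrom (default 6).
#' @param min_length Minimum reported inclusive length (default 6).
#' @return Tibble with columns `protein_id`, `start`, `end`, `length`.
#' @export
chain_return_lengths <- function(structure, cutoff = 6, min_length = 6) {
  cm <- compute_contacts(structure, cutoff,
                         min_separation = max(1, min_length - 1))
  tibble::tibble(protein_id = structure_id(structure),
                 start = cm$i, end = cm$j, length = cm$j - cm$i + 1)
}

#' Restrict chain returns to binding-site loops
#'
#' Keeps loops where at least one end residue lies in the protein's
#' annotated ligand-binding site. Proteins without an annotation are
#' skipped with a warning.
#'
#' @param loops Tibble from [chain_return_lengths()] (may pool proteins).
#' @param sites Annotation tibble with columns `protein_id`, `residue`
#'   (one row per binding-site residue).
#' @return Filtered loops tibble.
#' @export
binding_site_filter <- function(loops, sites) {
  missing <- setdiff(unique(loops$protein_id), unique(sites$protein_id))
  if (length(missing) > 0) {
    warn(sprintf("no binding-site annotation for: %s; skipped",
                 paste(missing, collapse = ", ")))
    loops <- loops[!loops$protein_id %in% missing, , drop = FALSE]
  }
  keep <- purrr::map_lgl(seq_len(nrow(loops)), function(k) {
    site <- sites$residue[sites$protein_id == loops$protein_id[k]]
    loops$start[k] %in% site || loops$end[k] %in% site
  })
  loops[keep, , drop = FALSE]
}

#' Loop-length distribution
#'
#' Bins lengths with width 1 and normalizes to a density. `"pooled"`
#' treats all loops as one sample; `"per_protein"` averages per-protein
#' densities so every protein contributes equally.
#'
#' @param loops Tibble with `protein_id` and `length` columns.
#' @param normalize `"pooled"` or `"per_protein"`.
#' @return Tibble with columns `length`, `count`, `density`.
#' @export
aggregate_distribution <- function(loops,
                                   normalize = c("pooled", "per_protein")) {
  normalize <- match.arg(normalize)
  stop_unless(nrow(loops) > 0, "no loops to aggregate")
  lengths <- sort(unique(loops$length))
  bins <- seq(min(lengths), max(lengths))
  if (normalize == "pooled") {
    count <- vapply(bins, function(b) sum(loops$length == b), numeric(1))
    density <- count / sum(count)
  } else {
    per <- purrr::map(split(loops$length, loops$protein_id), function(l)
      vapply(bins, function(b) sum(l == b) / length(l), numeric(1)))
    density <- rowMeans(do.call(cbind, per))
    count <- vapply(bins, function(b) sum(loops$length == b), numeric(1))
  }
  tibble::tibble(length = bins, count = count, density = density)
}
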