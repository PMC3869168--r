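#' @title Contact persistence in trajectory snapshots
#' @description From multi-model snapshot coordinates, the fraction of
#' frames each residue pair spends in contact is compared to the mean
#' fraction of all pairs at the same sequence separation; pairs whose log
#' ratio exceeds a threshold are flagged as enriched, and their overlap
#' with the locks-plus-neighbours core is scored with a hypergeometric
#' test.
#' @name md_contact_analysis
NULL

#' Per-pair contact fractions over trajectory frames
#'
#' @param trajectory Multi-model structure tibble (>= 20 models/frames).
#' @param cutoff Heavy-atom cutoff in Angstrom (default 6).
#' @param min_separation Minimum `j - i` (default 3).
#' @return Tibble with columns `i`, `j`, `sep`, `fraction` for every pair
#'   in contact in at least one frame; attributes `L`, `n_frames`.
#' @export
contact_fractions <- function(trajectory, cutoff = 6, min_separation = 3) {
  nf <- n_models(trajectory)
  stop_unless(nf >= 20, "need >= 20 frames, got %d", nf)
  cm <- compute_contacts(trajectory, cutoff, min_separation,
                         model_policy = "all_models_any")
  per_frame <- purrr::map(sort(unique(trajectory$model)), function(m)
    model_contact_pairs(model_atoms(trajectory, m), cutoff, min_separation))
  counts <- dplyr::bind_rows(per_frame) |>
    dplyr::count(.data$i, .data$j, name = "n_hit")
  out <- dplyr::left_join(tibble::as_tibble(cm)[, c("i", "j", "sep")],
                          counts, by = c("i", "j")) |>
    dplyr::mutate(fraction = .data$n_hit / nf) |>
    dplyr::select(-"n_hit")
  attr(out, "L") <- structure_length(trajectory)
  attr(out, "n_frames") <- nf
  out
}

#' Expected contact fraction per sequence separation
#'
#' For each separation s, the mean fraction over *all* pairs at that
#' separation within the chain, counting the `L - s` possible pairs
#' including those never in contact.
#'
#' @param fractions Tibble from [contact_fractions()].
#' @param L Chain length; defaults to the attribute on `fractions`.
#' @return Tibble with columns `sep`, `baseline`, `n_pairs`.
#' @export
separation_baseline <- function(fractions, L = NULL) {
  stop_unless(nrow(fractions) > 0, "empty fraction table")
  L <- L %||% attr(fractions, "L") %||%
    abort("chain length L neither supplied nor attached")
  fractions |>
    dplyr::group_by(sep = .data$sep) |>
    dplyr::summarise(total = sum(.data$fraction), .groups = "drop") |>
    dplyr::mutate(n_pairs = L - .data$sep,
                  baseline = .data$total / .data$n_pairs) |>
    dplyr::select("sep", "baseline", "n_pairs")
}

#' Log ratio of observed to expected contact fractions
#'
#' `log_ratio = ln(fraction / baseline(sep))`. Under the default
#' `"enrichment"` convention a pair is flagged when
#' `log_ratio > flag_threshold` (more likely in contact than typical for
#' its separation); `"depletion_sign"` flags `log_ratio < -flag_threshold`
#' instead, for compatibility with analyses that report the ratio with
#' the opposite sign.
#'
#' @param fractions Tibble from [contact_fractions()].
#' @param baseline Tibble from [separation_baseline()].
#' @param flag_threshold Magnitude threshold (default 0.3).
#' @param convention `"enrichment"` (default) or `"depletion_sign"`.
#' @return `fractions` with `baseline`, `log_ratio` and logical `flagged`
#'   columns.
#' @export
contact_log_ratio <- function(fractions, baseline, flag_threshold = 0.3,
                              convention = c("enrichment",
                                             "depletion_sign")) {
  convention <- match.arg(convention)
  d <- dplyr::left_join(fractions, baseline[, c("sep", "baseline")],
                        by = "sep")
  stop_unless(all(!is.na(d$baseline) & d$baseline > 0),
              "baseline missing or zero at some separations")
  d$log_ratio <- log(d$fraction / d$baseline)
  d$flagged <- if (convention == "enrichment")
    d$log_ratio > flag_threshold else d$log_ratio < -flag_threshold
  d
}

#' Hypergeometric overlap of flagged contacts with the core
#'
#' Overlap = |flagged and core| / |flagged|; the p-value is the upper
#' hypergeometric tail for drawing `|flagged|` contacts from the full map
#' with `|core contacts|` marked.
#'
#' @param flagged Tibble of flagged pairs (columns `i`, `j`).
#' @param core `ln_core` from [build_core()] (or a tibble of core contact
#'   pairs).
#' @param full_map Full contact tibble (the sampling universe).
#' @return List with `overlap`, `p`, `n_flagged`, `n_core`, `n_total`,
#'   `n_overlap`.
#' @export
core_overlap_significance <- function(flagged, core, full_map) {
  stop_unless(nrow(flagged) > 0, "empty flagged set")
  core_pairs <- if (inherits(core, "ln_core")) core$contacts else core
  key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
  uni <- unique(key(full_map))
  ck <- intersect(unique(key(core_pairs)), uni)
  fk <- intersect(unique(key(flagged)), uni)
  x <- length(intersect(fk, ck))
  list(overlap = x / length(fk),
       p = phyper(x - 1, length(ck), length(uni) - length(ck),
                  length(fk), lower.tail = FALSE),
       n_flagged = length(fk), n_core = length(ck),
       n_total = length(uni), n_overlap = x)
}
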