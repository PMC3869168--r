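#' @title Contact-topology metrics
#' @description Contact order CO = (1/(L N)) sum |i - j| and total contact
#' distance TCD = (1/L^2) sum |i - j|, with absolute variants ACO = CO x L
#' and ATCD = TCD x L, evaluated over any contact subset. TCD's
#' normalisation by L^2 (rather than L N) makes it insensitive to whether
#' near neighbours are included, which is what makes it usable on
#' restricted contact subsets such as the locks-plus-neighbours core.
#' @name folding_metrics
NULL

# Normalise a pair specification to a deduplicated tibble(i, j, sep).
as_pairs <- function(pairs) {
  if (is.matrix(pairs)) pairs <- tibble::tibble(i = pairs[, 1],
                                                j = pairs[, 2])
  stop_unless(all(c("i", "j") %in% names(pairs)),
              "pairs must have columns i and j")
  p <- tibble::tibble(i = pmin(pairs$i, pairs$j),
                      j = pmax(pairs$i, pairs$j))
  p <- dplyr::distinct(p)
  p$sep <- p$j - p$i
  p
}

#' Contact order of a contact subset
#'
#' @param pairs Contact tibble (or two-column matrix) of residue pairs;
#'   duplicates are removed.
#' @param L Chain length; defaults to the `L` attribute of `pairs`.
#' @return CO (unitless scalar).
#' @export
#' @examples
#' contact_order(data.frame(i = 1, j = 8), L = 10)  # 0.7
contact_order <- function(pairs, L = NULL) {
  L <- contacts_L(pairs, L)
  p <- as_pairs(pairs)
  stop_unless(nrow(p) >= 1, "empty contact subset")
  sum(p$sep) / (L * nrow(p))
}

#' Total contact distance of a contact subset
#'
#' @inheritParams contact_order
#' @return TCD (unitless scalar).
#' @export
#' @examples
#' total_contact_distance(data.frame(i = 1, j = 8), L = 10)  # 0.07
total_contact_distance <- function(pairs, L = NULL) {
  L <- contacts_L(pairs, L)
  p <- as_pairs(pairs)
  stop_unless(nrow(p) >= 1, "empty contact subset")
  sum(p$sep) / L^2
}

#' All four contact metrics at once
#'
#' @inheritParams contact_order
#' @param subset Label for the contact subset (`"all"`, `"core"`,
#'   `"non_core"`, ...).
#' @param protein_id Protein id; defaults to the `id` attribute of `pairs`.
#' @return Tibble with columns `protein_id`, `metric`
#'   (CO/ACO/TCD/ATCD), `value`, `n_contacts`, `subset`.
#' @export
contact_metrics <- function(pairs, L = NULL, subset = "all",
                            protein_id = NULL) {
  L <- contacts_L(pairs, L)
  protein_id <- protein_id %||% attr(pairs, "id") %||% "protein"
  p <- as_pairs(pairs)
  stop_unless(nrow(p) >= 1, "empty contact subset")
  co <- sum(p$sep) / (L * nrow(p))
  tcd <- sum(p$sep) / L^2
  tibble::tibble(protein_id = protein_id,
                 metric = c("CO", "ACO", "TCD", "ATCD"),
                 value = c(co, co * L, tcd, tcd * L),
                 n_contacts = nrow(p), subset = subset)
}

#' Correlate a metric with log folding rates
#'
#' Least-squares regression of `ln_kf` on the metric across proteins,
#' reporting the squared Pearson correlation.
#'
#' @param values Tibble with columns `protein_id` and `value` (one row per
#'   protein).
#' @param rates Tibble with columns `protein_id` and `ln_kf`.
#' @return An object of class `ln_corr` with elements `r2`, `slope`,
#'   `intercept`, `n`, `fit` (the `lm` object), `data` and optional
#'   `empirical_p`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
correlate_lnkf <- function(values, rates) {
  d <- dplyr::inner_join(values, rates, by = "protein_id")
  d <- d[complete.cases(d[, c("value", "ln_kf")]), , drop = FALSE]
  stop_unless(nrow(d) >= 3, "need at least 3 matched proteins, got %d",
              nrow(d))
  stop_unless(var(d$value) > 0,
              "metric is constant across proteins; correlation undefined")
  fit <- lm(ln_kf ~ value, data = d)
  structure(list(
    r2 = cor(d$value, d$ln_kf)^2,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n = nrow(d), fit = fit, data = tibble::as_tibble(d),
    empirical_p = NULL
  ), class = "ln_corr")
}

#' @export
print.ln_corr <- function(x, ...) {
  cat(sprintf(
    "<ln k_f ~ metric> n = %d proteins, r^2 = %.3f, slope = %.3g, intercept = %.3g%s\n",
    x$n, x$r2, x$slope, x$intercept,
    if (!is.null(x$empirical_p))
      sprintf(", empirical p = %.4g", x$empirical_p) else ""))
  invisible(x)
}

# Sample residues uniformly without replacement until the induced contact
# count (both endpoints sampled) reaches k, then thin to exactly k.
sample_induced_contacts <- function(contacts, L, k) {
  stop_unless(k <= nrow(contacts),
              "k_contacts (%d) exceeds the %d available contacts", k,
              nrow(contacts))
  member <- logical(L)
  hit <- logical(nrow(contacts))
  n_hit <- 0
  for (r in sample.int(L)) {
    member[r] <- TRUE
    new_hit <- !hit & ((contacts$i == r & member[contacts$j]) |
                         (contacts$j == r & member[contacts$i]))
    hit <- hit | new_hit
    n_hit <- n_hit + sum(new_hit)
    if (n_hit >= k) break
  }
  idx <- which(hit)
  if (length(idx) > k) idx <- sample(idx, k)
  contacts[idx, , drop = FALSE]
}

#' Random-contact-subset null control
#'
#' For each replicate and protein, residues are selected uniformly at
#' random (without replacement) until the contacts induced among them
#' reach the target count, the induced set is thinned to exactly that
#' count, TCD is recomputed, and the cross-protein r^2 against `ln_kf` is
#' recorded. The empirical p-value for an observed r^2 uses the one-sided
#' add-one rule `(1 + #\{null >= observed\}) / (n_reps + 1)`.
#'
#' @param cohort Tibble with columns `protein_id`, `L` and a `contacts`
#'   list-column of full contact tibbles (see [build_cohort()]).
#' @param rates Tibble with `protein_id`, `ln_kf`.
#' @param k_contacts Named integer vector (names = protein ids) of target
#'   contact counts per protein, e.g. core-contact counts.
#' @param n_reps Number of null replicates (>= 100).
#' @param seed RNG seed (the whole null distribution is reproducible).
#' @param observed_r2 Observed r^2 to score; `NULL` returns only the null.
#' @return List with `null_r2` (length `n_reps`), `observed_r2` and
#'   `empirical_p` (`NULL` when no observed value given).
#' @export
random_contact_control <- function(cohort, rates, k_contacts, n_reps = 1000,
                                   seed = 1, observed_r2 = NULL) {
  stop_unless(n_reps >= 100, "n_reps must be >= 100")
  ids <- cohort$protein_id
  stop_unless(all(ids %in% names(k_contacts)),
              "k_contacts must be named for every cohort protein")
  null_r2 <- with_seed_if(seed, vapply(seq_len(n_reps), function(rep) {
    vals <- vapply(seq_along(ids), function(p) {
      sub <- sample_induced_contacts(cohort$contacts[[p]], cohort$L[p],
                                     k_contacts[[ids[p]]])
      sum(sub$j - sub$i) / cohort$L[p]^2
    }, numeric(1))
    d <- dplyr::inner_join(tibble::tibble(protein_id = ids, value = vals),
                           rates, by = "protein_id")
    cor(d$value, d$ln_kf)^2
  }, numeric(1)))
  p <- if (is.null(observed_r2)) NULL else
    (1 + sum(null_r2 >= observed_r2)) / (n_reps + 1)
  list(null_r2 = null_r2, observed_r2 = observed_r2, empirical_p = p)
}

#' Scan the TCD correlation over sequence-separation windows
#'
#' Restricts every protein's contacts to
#' `min_sep <= j - i <= max_sep`, recomputes TCD and the correlation with
#' `ln_kf`, one point per entry of `min_sep_grid`. Proteins with no
#' contacts left in a window are dropped from that point with a warning.
#'
#' @inheritParams random_contact_control
#' @param min_sep_grid Integer vector of minimum separations (default
#'   2:54).
#' @param max_sep Optional maximum separation (e.g. 80); `NULL` = none.
#' @return Tibble with columns `min_sep`, `max_sep`, `n_proteins`, `r2`.
#' @export
separation_scan <- function(cohort, rates, min_sep_grid = 2:54,
                            max_sep = NULL) {
  stop_unless(length(min_sep_grid) > 0, "empty separation grid")
  purrr::map_dfr(min_sep_grid, function(ms) {
    vals <- purrr::map_dbl(seq_len(nrow(cohort)), function(p) {
      sep <- cohort$contacts[[p]]$sep
      keep <- sep >= ms & (is.null(max_sep) | sep <= (max_sep %||% Inf))
      if (!any(keep)) return(NA_real_)
      sum(sep[keep]) / cohort$L[p]^2
    })
    if (anyNA(vals)) {
      warn(sprintf(
        "separation window [%d, %s] leaves no contacts for: %s", ms,
        max_sep %||% "Inf",
        paste(cohort$protein_id[is.na(vals)], collapse = ", ")))
    }
    d <- dplyr::inner_join(
      tibble::tibble(protein_id = cohort$protein_id, value = vals),
      rates, by = "protein_id")
    d <- d[complete.cases(d), , drop = FALSE]
    tibble::tibble(min_sep = ms, max_sep = max_sep %||% Inf,
                   n_proteins = nrow(d),
                   r2 = if (nrow(d) >= 3 && var(d$value) > 0)
                     cor(d$value, d$ln_kf)^2 else NA_real_)
  })
}

#' Assemble an analysis cohort from structures
#'
#' Builds the tabular per-protein container used by the correlation,
#' control, scan and elimination functions: one row per protein with
#' list-columns for the structure, its metric contact map and its
#' per-residue properties.
#'
#' @param structures Named list of structure tibbles (names become
#'   protein ids; unnamed lists fall back to each structure's own id).
#' @param cutoff Contact cutoff in Angstrom (default 6).
#' @param min_separation Metric contact separation (default 3).
#' @return Tibble with columns `protein_id`, `L`, `structure`, `contacts`,
#'   `properties`.
#' @export
build_cohort <- function(structures, cutoff = 6, min_separation = 3) {
  ids <- names(structures) %||% purrr::map_chr(structures, structure_id)
  if (is.null(names(structures))) names(structures) <- ids
  tibble::tibble(
    protein_id = ids,
    L = purrr::map_int(structures, function(s)
      as.integer(structure_length(s))),
    structure = unname(structures),
    contacts = purrr::map(structures, compute_contacts, cutoff = cutoff,
                          min_separation = min_separation),
    properties = purrr::map(structures, residue_properties, cutoff = cutoff)
  )
}
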