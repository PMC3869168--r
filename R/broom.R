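#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metric / folding-rate correlation
#'
#' @param x An `ln_corr` object from [correlate_lnkf()].
#' @param ... Unused.
#' @return One row per regression term (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @export
tidy.ln_corr <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4])
}

#' One-row summary of a metric / folding-rate correlation
#'
#' @param x An `ln_corr` object.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `slope`, `intercept`, `n`,
#'   `p.value` (of the slope) and `empirical.p` (from the random-contact
#'   control, `NA` when not attached).
#' @export
glance.ln_corr <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(r.squared = x$r2, slope = x$slope,
                 intercept = x$intercept, n = x$n,
                 p.value = sm[2, 4],
                 empirical.p = x$empirical_p %||% NA_real_)
}

#' Tidy a locks-plus-neighbours core
#'
#' @param x An `ln_core` object from [build_core()].
#' @param ... Unused.
#' @return The core contact tibble with an `in_minimal_pair` flag per
#'   endpoint.
#' @export
tidy.ln_core <- function(x, ...) {
  dplyr::mutate(x$contacts,
                i_in_pair = .data$i %in% x$minimal_pairs,
                j_in_pair = .data$j %in% x$minimal_pairs)
}

#' One-row summary of a locks-plus-neighbours core
#'
#' @param x An `ln_core` object.
#' @param ... Unused.
#' @return Tibble with `n_core_residues`, `n_core_contacts`,
#'   `n_minimal_pairs`, `L` and the residue/contact percentages when `L`
#'   is known.
#' @export
glance.ln_core <- function(x, ...) {
  tibble::tibble(n_core_residues = length(x$residues),
                 n_core_contacts = nrow(x$contacts),
                 n_minimal_pairs = length(x$minimal_pairs),
                 L = x$L %||% NA_integer_,
                 residue_pct = if (!is.null(x$L))
                   100 * length(x$residues) / x$L else NA_real_)
}
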