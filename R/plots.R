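#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contact map
#'
#' @param object Contact tibble from [compute_contacts()].
#' @param ... Unused.
#' @return A ggplot: contacts as tiles in the (i, j) plane, mirrored
#'   about the diagonal, coloured by minimum heavy-atom distance.
#' @export
autoplot.ln_contacts <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(x = object$i, y = object$j, dist = object$dist),
    tibble::tibble(x = object$j, y = object$i, dist = object$dist))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  fill = .data$dist)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "min dist (Å)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue i", y = "residue j",
                  title = attr(object, "id")) +
    ggplot2::theme_minimal()
}

#' Plot a metric / folding-rate correlation
#'
#' @param object `ln_corr` object from [correlate_lnkf()].
#' @param ... Unused.
#' @return A ggplot: ln k_f against the metric with the least-squares
#'   line and the r^2 in the subtitle.
#' @export
autoplot.ln_corr <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$value, .data$ln_kf)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "metric", y = expression(ln ~ k[f]),
                  subtitle = sprintf("r^2 = %.2f over %d proteins",
                                     object$r2, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot an elimination curve with its random-removal envelope
#'
#' @param object `ln_elim` tibble from [elimination_curve()].
#' @param ... Unused.
#' @return A ggplot: mean r^2 of the property-ranked removal against the
#'   percentage removed, over the 5-95% (and 1-99%) random envelopes.
#' @export
autoplot.ln_elim <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$percent)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p1, ymax = .data$p99),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_r2,
                                    colour = .data$property),
                       linewidth = 1) +
    ggplot2::labs(x = "% residues removed", y = expression(r^2),
                  colour = "ranking") +
    ggplot2::theme_minimal()
}

#' Plot a rigidity autocorrelation curve
#'
#' @param object `ln_autocorr` tibble from [rigidity_autocorrelation()].
#' @param ... Unused.
#' @return A ggplot of C(L) against lag L with the 22-27 peak window
#'   shaded.
#' @export
autoplot.ln_autocorr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$L, .data$C)) +
    ggplot2::annotate("rect", xmin = 22, xmax = 27, ymin = -Inf,
                      ymax = Inf, fill = "grey90") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue separation L", y = "C(L)") +
    ggplot2::theme_minimal()
}

#' Plot a loop-length distribution
#'
#' @param distribution Tibble from [aggregate_distribution()], optionally
#'   several row-bound with a `subset` column.
#' @return A ggplot of density against loop length.
#' @export
plot_loop_lengths <- function(distribution) {
  aes <- if ("subset" %in% names(distribution))
    ggplot2::aes(.data$length, .data$density, colour = .data$subset)
  else ggplot2::aes(.data$length, .data$density)
  ggplot2::ggplot(distribution, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "loop length (residues)", y = "density") +
    ggplot2::theme_minimal()
}
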