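#' Plot character fit indices against age
#'
#' Faceted scatter of CI, RI, RC, HI and Goloboff fit against character age
#' `nd` — the homoplasy-versus-age diagnostic. Excellent fit of ancient
#' characters shows as index values near 1 at low `nd`.
#'
#' @param object a [character_fit()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.truc_charfit <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("ci", "ri", "rc", "hi", "g_fit"),
                        names_to = "index", values_to = "value") |>
    mutate(index = factor(.data$index,
                          levels = c("ci", "ri", "rc", "hi", "g_fit"),
                          labels = c("CI", "RI", "RC", "HI", "G-fit")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$nd, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$index)) +
    ggplot2::labs(x = "character age (nd)", y = "index value") +
    ggplot2::theme_bw()
}

#' Plot an ordination
#'
#' First two principal coordinates, coloured by group, with % variance in
#' the axis labels.
#'
#' @param object a `truc_pcoa` object.
#' @param axes pair of axes to draw (default first and second).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.truc_pcoa <- function(object, axes = c(1, 2), ...) {
  pts <- object$points
  ax <- paste0("axis_", axes)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                    colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCo%d (%.1f%%)", axes[1], object$var_pct[axes[1]]),
      y = sprintf("PCo%d (%.1f%%)", axes[2], object$var_pct[axes[2]])) +
    ggplot2::theme_bw()
}

#' Plot rhizome donor composition
#'
#' @param object an [aggregate_rhizome()] tibble.
#' @param ... unused.
#' @return A ggplot bar chart of donor-class percentages.
#' @export
autoplot.truc_rhizome <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$donor, y = .data$pct,
                               fill = .data$donor)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "donor class", y = "% of genes") +
    ggplot2::theme_bw()
}

#' Bar chart of Venn sharing-pattern counts
#'
#' @param patterns a [sharing_patterns()] tibble.
#' @return A ggplot object.
#' @export
plot_sharing_patterns <- function(patterns) {
  ggplot2::ggplot(patterns,
                  ggplot2::aes(x = stats::reorder(.data$pattern, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "group sharing pattern", y = "features") +
    ggplot2::theme_bw()
}
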