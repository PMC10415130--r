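# ggplot2 visualisations for trajectories, skew ensembles, ratio
# diagnostics and timing distributions.

#' Plot a base-content trajectory
#'
#' @param object A `pr2_trajectory` tibble from [evolve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pr2_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(base_order()),
                              names_to = "base", values_to = "content")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_byr, .data$content,
                                     colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (byr)", y = "base content",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Skew scatter with PR-2 tolerance boxes
#'
#' 2D view of final (GC skew, AT skew) pairs of an ensemble with the
#' per-kingdom compliance boxes overlaid.
#'
#' @param skew_tbl Tibble with `gc_skew` and `at_skew` columns.
#' @param boxes Tolerance-box tibble (default all three kingdoms).
#' @param zoom Optional half-widths `c(gc, at)` to zoom around 0.
#' @return A ggplot.
#' @export
plot_skew_plane <- function(skew_tbl, boxes = tolerance_boxes(),
                            zoom = NULL) {
  p <- ggplot2::ggplot(skew_tbl,
                       ggplot2::aes(.data$gc_skew, .data$at_skew)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_rect(
      data = boxes, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$gc_mean - .data$gc_sd,
                   xmax = .data$gc_mean + .data$gc_sd,
                   ymin = .data$at_mean - .data$at_sd,
                   ymax = .data$at_mean + .data$at_sd,
                   colour = .data$kingdom),
      fill = NA, linetype = "dashed"
    ) +
    ggplot2::labs(x = "GC skew (G - C)/(G + C)",
                  y = "AT skew (A - T)/(A + T)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(zoom)) {
    p <- p + ggplot2::coord_cartesian(xlim = c(-zoom[1], zoom[1]),
                                      ylim = c(-zoom[2], zoom[2]))
  }
  p
}

#' Plot NSB pair-ratio distributions
#'
#' Faceted histograms of the six reverse-complement rate-pair ratios, split
#' by PR-2 compliance, with the ratio-1 reference line.
#'
#' @param object A `pr2_ratio_diag` from [nsb_ratio_diagnostics()].
#' @param max_ratio Truncate display at this ratio.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pr2_ratio_diag <- function(object, max_ratio = 5, ...) {
  df <- object$ratios[object$ratios$ratio <= max_ratio, ]
  df$subset <- ifelse(df$compliant, "PR-2 compliant", "non-compliant")
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio)) +
    ggplot2::geom_histogram(breaks = seq(0, max_ratio, by = 0.25)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::facet_grid(subset ~ pair, scales = "free_y") +
    ggplot2::labs(x = "rate ratio (pair member 1 / member 2)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot timing distributions
#'
#' Overlaid histograms of time to PR-2 compliance and time to compositional
#' equilibration, with the 4.28-byr reference line.
#'
#' @param object A `pr2_timing` from [timing_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pr2_timing <- function(object, ...) {
  r <- object$replicates
  long <- dplyr::bind_rows(
    tibble::tibble(time = r$t_pr2, what = "time to PR-2"),
    tibble::tibble(time = r$t_eq, what = "time to equilibration")
  )
  long <- long[!is.na(long$time), ]
  ggplot2::ggplot(long, ggplot2::aes(.data$time, fill = .data$what)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 60) +
    ggplot2::geom_vline(xintercept = 4.28, linetype = "dashed") +
    ggplot2::labs(x = "time (byr)", y = "replicates", fill = NULL) +
    ggplot2::theme_minimal()
}
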