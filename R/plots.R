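#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a segmentation as per-chromosome class tracks
#'
#' One horizontal track per chromosome with segments coloured by class.
#' Zero-width breakpoints are drawn as vertical ticks.
#'
#' @param object A `segmentation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmentation <- function(object, ...) {
  d <- tidy(object)
  lens <- chrom_lengths(segmentation_layout(object))
  d$chrom <- factor(d$chrom, levels = names(lens))
  pos <- d[d$width > 0, ]
  zero <- d[d$width == 0, ]
  p <- ggplot2::ggplot(pos) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = 0, ymax = 1, fill = .data$class
    )) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom), switch = "y") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "class") +
    ggplot2::theme_minimal()
  if (nrow(zero) > 0) {
    p <- p + ggplot2::geom_segment(
      data = zero,
      ggplot2::aes(x = .data$start, xend = .data$start, y = 0, yend = 1),
      colour = "black", linewidth = 0.3
    )
  }
  p
}

#' Plot per-unit scrambling indices
#'
#' A bar per unit with the length-weighted mean as a dashed line; units
#' without aligned sequence are omitted.
#'
#' @param object A `scrambling_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scrambling_report <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!is.na(d$index), ]
  d$unit <- factor(d$unit, levels = d$unit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$index)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = weighted_scrambling_index(object),
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "scrambling index",
                  title = paste0("Strand-randomisation index by ",
                                 attr(object, "grouping"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a percent-length binned profile
#'
#' Mean value against bin midpoint in percent of chromosome length.
#'
#' @param object A `binned_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_profile <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d[!is.na(d$mean_value), ],
                  ggplot2::aes(x = .data$pct_mid, y = .data$mean_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "% of chromosome length", y = "mean value") +
    ggplot2::theme_minimal()
}

#' Plot boundary enrichment profiles
#'
#' Fraction of boundaries covered against offset, one panel per segment
#' class and boundary side, coloured by track.
#'
#' @param object An `enrichment_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!is.na(d$fraction), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$fraction,
                                  colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class),
                        cols = ggplot2::vars(.data$side)) +
    ggplot2::labs(x = "offset from boundary (bp)",
                  y = "fraction of boundaries covered") +
    ggplot2::theme_minimal()
}

#' Macrosynteny dot plot
#'
#' Ortholog pair midpoints, target position against query position,
#' facetted by chromosome pair.
#'
#' @param pairs A dot-plot table from [dotplot_table()], or a pair table
#'   accepted by it.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(pairs, ...) {
  d <- as_tibble(pairs)
  if (!all(c("t_pos", "q_pos") %in% names(d))) d <- dotplot_table(d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_pos, y = .data$q_pos)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$q_chrom),
                        cols = ggplot2::vars(.data$t_chrom),
                        scales = "free") +
    ggplot2::labs(x = "target position (bp)", y = "query position (bp)") +
    ggplot2::theme_minimal()
}
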