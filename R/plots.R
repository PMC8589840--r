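#' Plot a local Z-score shift profile
#'
#' @param object A `local_z_profile` from [local_z_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot local_z_profile
#' @export
autoplot.local_z_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$shift, y = .data$z)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hotspot shift (bp)", y = "association Z score") +
    ggplot2::theme_minimal()
}

#' Plot a genome-wide LOD curve
#'
#' LOD per marker, faceted by chromosome, with the permutation threshold as
#' a dashed line and significant peaks highlighted.
#'
#' @param object A `qtl_scan` from [map_qtl()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qtl_scan
#' @export
autoplot.qtl_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$scan,
                       ggplot2::aes(x = .data$pos / 1e3, y = .data$lod)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "LOD",
                  title = object$environment) +
    ggplot2::theme_minimal()
  if (nrow(object$peaks) > 0) {
    p <- p + ggplot2::geom_point(data = object$peaks,
                                 ggplot2::aes(x = .data$peak_pos / 1e3,
                                              y = .data$peak_lod),
                                 colour = "firebrick")
  }
  p
}

#' Genome-wide LOH map of one or more clones
#'
#' Draws each clone as a horizontal track per chromosome with LOH segments
#' as coloured bars (parent of origin) over the full chromosome extent.
#'
#' @param segments Output of [call_loh()].
#' @param layout A [genome_layout()].
#' @return A ggplot.
#' @export
plot_loh_map <- function(segments, layout) {
  chrom_bg <- tidyr::crossing(clone = unique(segments$clone),
                              tibble::as_tibble(layout)[, c("chrom", "length")])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = chrom_bg,
      ggplot2::aes(x = 0, xend = .data$length / 1e3,
                   y = .data$clone, yend = .data$clone),
      colour = "grey85", linewidth = 3) +
    ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start / 1e3, xend = .data$end / 1e3,
                   y = .data$clone, yend = .data$clone,
                   colour = .data$parent),
      linewidth = 3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(P1 = "#D55E00", P2 = "#0072B2")) +
    ggplot2::labs(x = "position (kb)", y = NULL, colour = "homozygous for") +
    ggplot2::theme_minimal()
}
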