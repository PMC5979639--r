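#' Manhattan plot of association z-scores
#'
#' SNP |z| (or z) along the genome, chromosomes concatenated, with the
#' kernel-smoothed track overlaid and outliers (q below the threshold)
#' highlighted.
#'
#' @param assoc tidy association table for one test (`chrom`, `pos`, `z`,
#'   optionally `q`).
#' @param track optional [smooth_zscores()] output to overlay.
#' @param q_threshold outliers are coloured when a `q` column is present.
#' @return A ggplot.
#' @export
plot_manhattan <- function(assoc, track = NULL, q_threshold = 0.05) {
  offsets <- assoc |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos)) |>
    dplyr::mutate(offset = dplyr::lag(cumsum(as.numeric(.data$len)),
                                      default = 0))
  df <- assoc |>
    dplyr::left_join(offsets, by = "chrom") |>
    dplyr::mutate(
      x = .data$pos + .data$offset,
      outlier = if ("q" %in% names(assoc)) .data$q < q_threshold else FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, abs(.data$z))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier),
                        size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "genome position", y = "|z|") +
    ggplot2::theme_minimal()
  if (!is.null(track)) {
    tr <- dplyr::left_join(track, offsets, by = "chrom") |>
      dplyr::mutate(x = .data$pos + .data$offset)
    p <- p + ggplot2::geom_line(
      data = tr, ggplot2::aes(.data$x, abs(.data$z_smooth)),
      colour = "steelblue", inherit.aes = FALSE)
  }
  p
}

#' Plot a smoothed z-score track
#'
#' @param object a `smoothed_track` tibble.
#' @param ... unused.
#' @return A ggplot faceted by chromosome.
#' @method autoplot smoothed_track
#' @export
autoplot.smoothed_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pos / 1e6, .data$z_smooth)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "smoothed z") +
    ggplot2::theme_minimal()
}

#' Plot an LD decay curve
#'
#' @param object an `ld_decay` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid / 1e3, .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
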