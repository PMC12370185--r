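# Figure helpers: positional supershift traces with SEM ribbons and MNase
# protection heatmaps.

#' Plot a positional supershift profile
#'
#' One trace per TFBS variant against the dyad offset, with an SEM ribbon
#' where at least two replicates contributed; gaps appear where nucleosome
#' formation was too inefficient to quantify.
#'
#' @param profile Tibble from [build_profile()].
#' @return A ggplot object.
#' @export
plot_supershift_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$dyad_offset, y = .data$mean,
                               colour = .data$tfbs_id,
                               fill = .data$tfbs_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~nps_id) +
    ggplot2::labs(x = "TFBS center offset from dyad (bp)",
                  y = "relative supershift (log2)",
                  colour = "TFBS", fill = "TFBS") +
    ggplot2::theme_minimal()
}

#' Plot an MNase protection heatmap
#'
#' Base position against digestion timepoint, shaded by per-base protection.
#'
#' @param protection Long tibble from [protection_matrix()] for one library
#'   sequence, with a `timepoint` column.
#' @return A ggplot object.
#' @export
plot_protection_heatmap <- function(protection) {
  ggplot2::ggplot(protection,
                  ggplot2::aes(x = .data$pos, y = factor(.data$timepoint),
                               fill = .data$protection)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "insert position (bp)", y = "MNase digestion (min)",
                  fill = "protection") +
    ggplot2::theme_minimal()
}
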