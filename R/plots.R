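#' Plot per-chip Z* scores of a screen
#'
#' Strip plot of Z* by role with the inhibition-class boundaries, the
#' screen-level view used to judge control separation and hit depth.
#'
#' @param scores Scored chips from [score_chips()].
#' @return A ggplot.
#' @export
plot_chip_scores <- function(scores) {
  ggplot2::ggplot(scores |> filter(!.data$qc_excluded),
                  ggplot2::aes(.data$role, .data$z_star,
                               colour = .data$inhibition_level)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(-3, -9, -15), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "robust Z*", colour = "inhibition") +
    ggplot2::theme_minimal()
}

#' Plot a detection overlay for one chip
#'
#' Debug view: detected nuclei over the raster, optionally with ground-truth
#' positions.
#'
#' @param image A `chip_image`.
#' @param nuclei Detections from [detect_nuclei()].
#' @param truth Optional ground-truth table (`x_um`, `y_um`).
#' @param downsample Keep every n-th pixel row/col in the raster backdrop.
#' @return A ggplot in chip coordinates (µm).
#' @export
plot_detection_overlay <- function(image, nuclei, truth = NULL, downsample = 2L) {
  px <- image$pixels
  rows <- seq(1L, nrow(px), by = downsample)
  cols <- seq(1L, ncol(px), by = downsample)
  um <- pixel_to_um(rep(rows, times = length(cols)),
                    rep(cols, each = length(rows)), image$geometry)
  backdrop <- tibble(x_um = um$x, y_um = um$y,
                     intensity = as.vector(px[rows, cols]))
  p <- ggplot2::ggplot(backdrop, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_point(data = nuclei, colour = "red", shape = 1, size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(data = truth, colour = "cyan",
                                 shape = 3, size = 1)
  }
  p
}

#' Plot pathway-combination frequencies of the hit list
#'
#' @param summaries Output of [combination_frequency()].
#' @return A ggplot bar chart with Z* mean +/- SD per combination.
#' @export
plot_pathway_combinations <- function(summaries) {
  df <- summaries |>
    mutate(pathway_combination = stats::reorder(.data$pathway_combination,
                                                .data$n_hits))
  ggplot2::ggplot(df, ggplot2::aes(.data$n_hits, .data$pathway_combination)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f ± %.1f",
                                                    .data$z_star_mean,
                                                    tidyr::replace_na(.data$z_star_sd, 0))),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "hit compounds", y = NULL) +
    ggplot2::theme_minimal()
}
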