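#' Plot a spectrogram image
#'
#' @param object A `spectrogram_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrogram_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$values)),
    col = seq_len(ncol(object$values))
  )
  df$time <- object$frame_times[df$col]
  df$frequency <- object$bin_frequencies[df$row]
  df$db <- as.vector(t(object$values))  # row-major over (row, col) grid
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot phase annotations from one or more sources
#'
#' Draws each source's events as coloured bars on its own row, per
#' recording, which makes boundary disagreements between annotators or
#' between an annotator and a detector directly visible.
#'
#' @param x Annotation tibble (any number of recordings and sources).
#' @return A ggplot.
#' @export
plot_annotations <- function(x) {
  x <- validate_annotations(x)
  ggplot2::ggplot(x) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = as.integer(factor(.data$source_id)) - 0.4,
      ymax = as.integer(factor(.data$source_id)) + 0.4,
      fill = .data$phase
    ), alpha = 0.8) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(x$source_id)),
      labels = sort(unique(x$source_id))
    ) +
    ggplot2::scale_fill_manual(
      values = c(inspiration = "#d7301f", expiration = "#fdcc8a")
    ) +
    ggplot2::facet_wrap(~recording_id, ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = NULL, fill = "Phase") +
    ggplot2::theme_minimal()
}

#' @rdname pseudo_kappa
#' @param object A `pseudo_kappa` object.
#' @export
autoplot.pseudo_kappa <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scope, y = .data$kappa)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.1
    ) +
    ggplot2::geom_hline(yintercept = c(0.6, 0.8), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "Pseudo-kappa", x = NULL) +
    ggplot2::theme_minimal()
}
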