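# ggplot2 autoplot methods for result objects

#' Plot an FCD matrix
#'
#' Heat map of window-by-window FC correlations; recurring connectivity
#' patterns appear as off-diagonal blocks.
#'
#' @param object an `fcd_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fcd_matrix <- function(object, ...) {
  m <- unclass_matrix(object)
  df <- tidyr::expand_grid(w1 = seq_len(nrow(m)), w2 = seq_len(ncol(m)))
  df$value <- as.numeric(m)[(df$w2 - 1) * nrow(m) + df$w1]
  ggplot2::ggplot(df, ggplot2::aes(.data$w1, .data$w2, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = "window", y = "window", title = "FCD matrix") +
    ggplot2::coord_equal()
}

#' Plot a reconstruction-error curve
#'
#' Source-latent correlation against the bottleneck dimension, with the
#' selection threshold and the selected dimension marked.
#'
#' @param object an `embedding_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.embedding_report <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(.data$d, .data$correlation)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$corr_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "bottleneck dimension d",
                  y = "source-latent correlation")
  if (!is.na(object$selected_d)) {
    p <- p + ggplot2::geom_vline(xintercept = object$selected_d,
                                 linetype = "dotted")
  }
  p
}

#' Plot a peak-agreement curve
#'
#' Mean source-latent event agreement per bottleneck dimension with one-SD
#' ribbons.
#'
#' @param object an `agreement_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.agreement_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$d, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "bottleneck dimension d", y = "peak agreement")
}

#' Plot an RSS trace with detected events
#'
#' @param object a `peak_set`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.peak_set <- function(object, ...) {
  df <- tidy.peak_set(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$rss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_point(data = df[df$flagged, ], colour = "firebrick") +
    ggplot2::geom_point(data = df[df$excluded, ], shape = 4) +
    ggplot2::labs(x = "frame", y = "RSS co-fluctuation amplitude")
}

#' Plot a classification report
#'
#' Per-repeat AUC values with the mean marked.
#'
#' @param object a `classification_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- tibble::tibble(repeat_id = object$repeat_id, auc = object$auc)
  ggplot2::ggplot(df, ggplot2::aes(.data$repeat_id, .data$auc)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "auc_mean"),
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "repeat", y = "held-out AUC")
}

#' Plot recovery trajectories
#'
#' Patient FC distance to the control reference and SC-FC coupling across
#' timepoints.
#'
#' @param object a `recovery_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.recovery_report <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trajectories,
                            c("fc_distance", "sc_fc"),
                            names_to = "metric", values_to = "value")
  tps <- unique(object$trajectories$timepoint)
  tr$timepoint <- factor(tr$timepoint, levels = tps)
  ggplot2::ggplot(tr, ggplot2::aes(.data$timepoint, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "timepoint post-stroke", y = NULL)
}

#' Plot a t-SNE projection
#'
#' @param projection tibble from [tsne_project()].
#' @return a ggplot with group centroids marked by asterisks.
#' @export
plot_tsne <- function(projection) {
  cent <- dplyr::summarise(dplyr::group_by(projection, .data$group),
                           tsne1 = mean(.data$tsne1),
                           tsne2 = mean(.data$tsne2), .groups = "drop")
  ggplot2::ggplot(projection,
                  ggplot2::aes(.data$tsne1, .data$tsne2,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = cent, shape = 8, size = 4,
                        show.legend = FALSE) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
}
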