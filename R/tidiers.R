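# broom-style tidiers for fitted objects and reports

#' Tidy an autoencoder training history
#'
#' @param x a `latent_ae`.
#' @param ... unused.
#' @return tibble with one row per epoch: epoch, train_loss, val_loss.
#' @export
tidy.latent_ae <- function(x, ...) x$history

#' One-row summary of a trained autoencoder
#'
#' @param x a `latent_ae`.
#' @param ... unused.
#' @return tibble: d, n_params, best_epoch, val_loss, val_correlation.
#' @export
glance.latent_ae <- function(x, ...) {
  tibble::tibble(
    d = x$d,
    n_params = sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 1)),
    best_epoch = x$best_epoch,
    val_loss = x$val_loss,
    val_correlation = x$val_correlation)
}

#' Tidy a reconstruction-curve report
#'
#' @param x an `embedding_report`.
#' @param ... unused.
#' @return the per-dimension curve tibble: d, val_loss, correlation.
#' @export
tidy.embedding_report <- function(x, ...) x$curve

#' @rdname tidy.embedding_report
#' @export
glance.embedding_report <- function(x, ...) {
  tibble::tibble(selected_d = x$selected_d,
                 corr_threshold = x$corr_threshold,
                 d_min = min(x$curve$d), d_max = max(x$curve$d))
}

#' Tidy a peak-agreement curve
#'
#' @param x an `agreement_curve`.
#' @param ... unused.
#' @return per-dimension tibble: d, mean, sd.
#' @export
tidy.agreement_curve <- function(x, ...) x$curve

#' Tidy a community partition
#'
#' @param x a `partition` from [modularity_signed()].
#' @param ... unused.
#' @return tibble: node, community.
#' @export
tidy.partition <- function(x, ...) {
  tibble::tibble(node = seq_along(x$membership), community = x$membership)
}

#' @rdname tidy.partition
#' @export
glance.partition <- function(x, ...) {
  tibble::tibble(n_communities = length(unique(x$membership)),
                 gamma = x$gamma, quality = x$quality)
}

#' Tidy a peak set
#'
#' @param x a `peak_set`.
#' @param ... unused.
#' @return tibble with one row per frame: frame, rss, flagged, excluded.
#' @export
tidy.peak_set <- function(x, ...) {
  tibble::tibble(frame = seq_len(x$n_frames), rss = x$rss,
                 flagged = seq_len(x$n_frames) %in% x$peaks,
                 excluded = seq_len(x$n_frames) %in% x$excluded)
}
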