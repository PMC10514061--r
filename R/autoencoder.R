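# dense autoencoder: mirrored encoder/decoder, Adam, early stopping

#' Autoencoder hyperparameters
#'
#' @param hidden widths of the encoder hidden layers (the decoder mirrors
#'   them). The bottleneck and output layers are linear; hidden layers use
#'   the activation below.
#' @param batch mini-batch size (reference protocol: 256 frames).
#' @param max_epochs training epoch cap (reference protocol: 100).
#' @param patience early-stopping patience in epochs without validation
#'   improvement.
#' @param learning_rate Adam step size.
#' @param val_frac fraction of frames held out as the validation split
#'   (reference protocol: 0.2).
#' @param activation `"relu"` (default) or `"linear"` (gives the network
#'   exactly linear capacity).
#' @return a named list of class `ae_hyper`.
#' @export
ae_hyper <- function(hidden = c(128, 64), batch = 256, max_epochs = 100,
                     patience = 10, learning_rate = 1e-3, val_frac = 0.2,
                     activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  structure(list(hidden = hidden, batch = batch, max_epochs = max_epochs,
                 patience = patience, learning_rate = learning_rate,
                 val_frac = val_frac, activation = activation),
            class = "ae_hyper")
}

relu <- function(x) pmax(x, 0)

ae_forward <- function(layers, acts, x, keep = FALSE) {
  zs <- vector("list", length(layers))
  as <- vector("list", length(layers) + 1)
  as[[1]] <- x
  for (l in seq_along(layers)) {
    z <- sweep(as[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    zs[[l]] <- z
    as[[l + 1]] <- if (acts[l]) relu(z) else z
  }
  if (keep) list(out = as[[length(as)]], zs = zs, as = as)
  else as[[length(as)]]
}

#' Train a dense autoencoder on concatenated frames
#'
#' Fits a mirrored dense autoencoder (encoder `n_roi -> hidden... -> d`,
#' decoder reversed; rectified-linear hidden units, linear bottleneck and
#' output) by minimising the mean-squared reconstruction error with Adam on
#' mini-batches, using a seeded frame-wise 80/20 train/validation split and
#' early stopping on the validation loss with best-weights restoration.
#'
#' @param frames matrix `n_roi x n_samples` of (z-scored) frames.
#' @param d bottleneck dimension, `1 <= d <= n_roi`.
#' @param hyper an [ae_hyper()] list.
#' @param seed integer seed controlling the split, the weight
#'   initialisation and the batch order; a fixed seed reproduces the loss
#'   history exactly.
#' @return a `latent_ae`: layers and biases, `d`, `history` tibble (epoch,
#'   train_loss, val_loss), `val_idx` (audit of the split),
#'   `val_correlation` (Pearson r between validation input and its
#'   reconstruction, flattened), `best_epoch`, `trained` flag.
#' @export
train_autoencoder <- function(frames, d, hyper = ae_hyper(), seed = 1) {
  abort_if(!is.matrix(frames), "frames must be a matrix (regions x samples)")
  n_roi <- nrow(frames)
  abort_if(d < 1 || d > n_roi, "need 1 <= d <= n_roi")
  x_all <- t(frames)
  n <- nrow(x_all)
  abort_if(n <= hyper$batch,
           "need more samples than the batch size; lower hyper$batch")
  hidden <- hyper$hidden[hyper$hidden < n_roi & hyper$hidden > d]
  widths <- c(n_roi, hidden, d, rev(hidden), n_roi)
  n_layers <- length(widths) - 1
  bottleneck <- length(hidden) + 1  # layer whose output is the latent code
  acts <- rep(hyper$activation == "relu", n_layers)
  acts[bottleneck] <- FALSE
  acts[n_layers] <- FALSE

  set.seed(seed)
  n_val <- max(1L, floor(hyper$val_frac * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- widths[l]
    sc <- if (acts[l]) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    layers[[l]] <- list(W = matrix(rnorm(widths[l] * widths[l + 1], sd = sc),
                                   widths[l], widths[l + 1]),
                        b = rep(0, widths[l + 1]))
  }
  mstate <- lapply(layers, function(L) list(W = L$W * 0, b = L$b * 0))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0

  xtr <- x_all[tr_idx, , drop = FALSE]
  xval <- x_all[val_idx, , drop = FALSE]
  hist <- vector("list", hyper$max_epochs)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(hyper$max_epochs)) {
    ord <- sample.int(nrow(xtr))
    starts <- seq(1, nrow(xtr), by = hyper$batch)
    bl <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- ord[starts[bi]:min(starts[bi] + hyper$batch - 1, nrow(xtr))]
      xb <- xtr[rows, , drop = FALSE]
      fw <- ae_forward(layers, acts, xb, keep = TRUE)
      resid <- fw$out - xb
      bl[bi] <- mean(resid^2)
      g <- 2 * resid / length(resid)
      step <- step + 1
      for (l in n_layers:1) {
        if (acts[l]) g <- g * (fw$zs[[l]] > 0)
        gW <- crossprod(fw$as[[l]], g)
        gb <- colSums(g)
        if (l > 1) g <- g %*% t(layers[[l]]$W)
        mstate[[l]]$W <- b1 * mstate[[l]]$W + (1 - b1) * gW
        mstate[[l]]$b <- b1 * mstate[[l]]$b + (1 - b1) * gb
        vstate[[l]]$W <- b2 * vstate[[l]]$W + (1 - b2) * gW^2
        vstate[[l]]$b <- b2 * vstate[[l]]$b + (1 - b2) * gb^2
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        layers[[l]]$W <- layers[[l]]$W -
          hyper$learning_rate * corr * mstate[[l]]$W / (sqrt(vstate[[l]]$W) + eps)
        layers[[l]]$b <- layers[[l]]$b -
          hyper$learning_rate * corr * mstate[[l]]$b / (sqrt(vstate[[l]]$b) + eps)
      }
    }
    val_out <- ae_forward(layers, acts, xval)
    val_loss <- mean((val_out - xval)^2)
    if (!is.finite(val_loss)) {
      stop(sprintf("divergence at epoch %d: non-finite validation loss", epoch),
           call. = FALSE)
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = mean(bl),
                                    val_loss = val_loss)
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, layers = layers, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= hyper$patience) break
    }
  }
  layers <- best$layers
  val_rec <- ae_forward(layers, acts, xval)
  model <- structure(list(layers = layers, acts = acts, widths = widths,
                          d = as.integer(d), bottleneck = bottleneck,
                          history = dplyr::bind_rows(hist),
                          val_idx = val_idx, seed = seed, hyper = hyper,
                          best_epoch = best$epoch,
                          val_loss = best$loss,
                          val_correlation = cor(as.numeric(xval),
                                                as.numeric(val_rec)),
                          trained = TRUE),
                     class = "latent_ae")
  model
}

#' @export
print.latent_ae <- function(x, ...) {
  cat(sprintf("<latent_ae> %s, d = %d, best epoch %d, val loss %.4g, val corr %.3f\n",
              paste(x$widths, collapse = "-"), x$d, x$best_epoch, x$val_loss,
              x$val_correlation))
  invisible(x)
}

#' Encode a series into the latent space
#'
#' Applies the trained encoder frame by frame; the output has `d` rows and
#' the same number of frames, tagged `space = "latent"`.
#'
#' @param model a trained `latent_ae`.
#' @param series a `subject_series` or matrix with `n_roi` rows.
#' @return a latent `subject_series`.
#' @export
encode_series <- function(model, series) {
  stopifnot(inherits(model, "latent_ae"))
  abort_if(!isTRUE(model$trained), "model is not trained")
  m <- as_series_matrix(series)
  abort_if(nrow(m) != model$widths[1],
           "series region count does not match the encoder input width")
  enc <- ae_forward(model$layers[seq_len(model$bottleneck)],
                    model$acts[seq_len(model$bottleneck)], t(m))
  out <- t(enc)
  if (inherits(series, "subject_series")) {
    subject_series(out,
                   subject_id = series_tag(series, "subject_id", "s1"),
                   timepoint = series_tag(series, "timepoint", "control"),
                   tr = series_tag(series, "tr", 2), space = "latent")
  } else out
}

#' Decode latent frames back to the source space
#'
#' @param model a trained `latent_ae`.
#' @param latent matrix `d x n_frames` (or latent `subject_series`).
#' @return matrix `n_roi x n_frames` of reconstructed frames.
#' @export
decode_frames <- function(model, latent) {
  stopifnot(inherits(model, "latent_ae"))
  m <- as_series_matrix(latent)
  abort_if(nrow(m) != model$d, "latent rows must equal the bottleneck d")
  idx <- (model$bottleneck + 1):length(model$layers)
  t(ae_forward(model$layers[idx], model$acts[idx], t(m)))
}

#' Reconstruct frames through the full autoencoder
#'
#' @param model a trained `latent_ae`.
#' @param frames matrix `n_roi x n_frames`.
#' @return reconstructed matrix of the same shape.
#' @export
reconstruct_frames <- function(model, frames) {
  decode_frames(model, encode_series(model, frames))
}

#' Reconstruction-error curve over bottleneck dimensions
#'
#' Trains one autoencoder per dimension (and per seed, averaging repeated
#' resplits), recording the validation loss and the source-latent
#' correlation (Pearson r between validation input frames and their
#' reconstruction, flattened). The selected dimension is the smallest whose
#' mean correlation reaches `corr_threshold`.
#'
#' @param frames matrix `n_roi x n_samples`.
#' @param d_range contiguous integer range of bottleneck dimensions.
#' @param hyper an [ae_hyper()] list.
#' @param seeds integer vector of split/initialisation seeds (each d is
#'   trained once per seed).
#' @param corr_threshold selection threshold on the mean correlation
#'   (default 0.9).
#' @return an `embedding_report`: list with `runs` (tibble: d, seed,
#'   val_loss, correlation), `curve` (tibble: d, val_loss, correlation,
#'   means over seeds), `selected_d`, `corr_threshold`, and `models` (the
#'   model trained with the first seed, per d).
#' @export
reconstruction_curve <- function(frames, d_range, hyper = ae_hyper(),
                                 seeds = 1, corr_threshold = 0.9) {
  abort_if(length(d_range) == 0, "d_range is empty")
  runs <- list()
  models <- list()
  for (d in d_range) {
    for (s in seeds) {
      fit <- tryCatch(train_autoencoder(frames, d, hyper, seed = s),
                      error = function(e) {
                        stop(sprintf("training failed at d = %d: %s", d,
                                     conditionMessage(e)), call. = FALSE)
                      })
      if (s == seeds[1]) models[[as.character(d)]] <- fit
      runs[[length(runs) + 1]] <- tibble::tibble(
        d = d, seed = s, val_loss = fit$val_loss,
        correlation = fit$val_correlation)
    }
  }
  runs <- dplyr::bind_rows(runs)
  curve <- dplyr::summarise(dplyr::group_by(runs, .data$d),
                            val_loss = mean(.data$val_loss),
                            correlation = mean(.data$correlation),
                            .groups = "drop")
  ok <- curve$d[curve$correlation >= corr_threshold]
  structure(list(runs = runs, curve = curve,
                 selected_d = if (length(ok)) min(ok) else NA_integer_,
                 corr_threshold = corr_threshold, models = models),
            class = "embedding_report")
}

#' @export
print.embedding_report <- function(x, ...) {
  cat(sprintf("<embedding_report> d in [%d, %d], selected d = %s (corr >= %.2f)\n",
              min(x$curve$d), max(x$curve$d),
              ifelse(is.na(x$selected_d), "none", x$selected_d),
              x$corr_threshold))
  print(x$curve)
  invisible(x)
}

#' Linear PCA baseline for the embedding
#'
#' Eigendecomposition of the frame covariance; frames are projected on the
#' top `d` components and reconstructed, for head-to-head comparison with
#' the autoencoder at the same dimension.
#'
#' @param frames matrix `n_roi x n_samples`.
#' @param d number of components, `<= n_roi`.
#' @return list with `components` (loadings), `variance_explained`
#'   (fraction in `[0, 1]`), `projected` (`d x n_samples`), `reconstructed`
#'   (`n_roi x n_samples`), `reconstruction_correlation`.
#' @export
pca_baseline <- function(frames, d) {
  abort_if(d > nrow(frames), "d cannot exceed the number of regions")
  pc <- prcomp(t(frames), center = TRUE, scale. = FALSE)
  varfrac <- sum(pc$sdev[seq_len(d)]^2) / sum(pc$sdev^2)
  proj <- t(pc$x[, seq_len(d), drop = FALSE])
  rec <- t(pc$x[, seq_len(d), drop = FALSE] %*%
             t(pc$rotation[, seq_len(d), drop = FALSE])) + pc$center
  list(components = pc$rotation[, seq_len(d), drop = FALSE],
       variance_explained = varfrac, projected = proj, reconstructed = rec,
       reconstruction_correlation = cor(as.numeric(frames), as.numeric(rec)))
}
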