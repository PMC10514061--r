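# feature construction, random-forest classification, behavior correlations

#' Build a subject-level feature table
#'
#' For each subject the chosen connectivity-derived matrix (full-frame FC
#' or the irreversibility matrix) is computed on the subject's series --
#' encoded through the autoencoder first for latent-space features -- and
#' summarised: the vectorised upper triangle, its mean, or its standard
#' deviation.
#'
#' @param cohort a `bold_cohort`.
#' @param space `"source"` or `"latent"` (the latter needs `latent_model`).
#' @param metric `"fc"` or `"irreversibility"`.
#' @param summary `"upper_triangle"`, `"mean"` or `"sd"`.
#' @param latent_model a trained [train_autoencoder()] model for latent
#'   features.
#' @param timepoint series selector (default `"acute"`).
#' @param subjects optional subject-id subset (e.g. patients only).
#' @return a `feature_table` tibble: subject_id, group, then feature
#'   columns `f1..fk`; attributes record the space, metric and summary.
#' @export
build_features <- function(cohort, space = c("source", "latent"),
                           metric = c("fc", "irreversibility"),
                           summary = c("upper_triangle", "mean", "sd"),
                           latent_model = NULL, timepoint = "acute",
                           subjects = NULL) {
  space <- match.arg(space)
  metric <- match.arg(metric)
  summary <- match.arg(summary)
  abort_if(space == "latent" && is.null(latent_model),
           "latent features need a trained latent_model")
  keys <- cohort_series_keys(cohort, timepoint)
  ids <- vapply(keys, function(k) series_tag(cohort$series[[k]], "subject_id", k), "")
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, ids)
    abort_if(length(missing) > 0,
             paste0("missing series for subject(s): ",
                    paste(missing, collapse = ", ")))
    keys <- keys[ids %in% subjects]
    ids <- ids[ids %in% subjects]
  }
  groups <- setNames(cohort$subjects$group, cohort$subjects$subject_id)
  feats <- lapply(keys, function(k) {
    s <- cohort$series[[k]]
    if (space == "latent") s <- encode_series(latent_model, s)
    m <- if (metric == "fc") fc_matrix(s) else irreversibility_matrix(s)
    u <- upper_tri(unclass_matrix(m))
    switch(summary, upper_triangle = u, mean = mean(u), sd = sd(u))
  })
  fm <- do.call(rbind, feats)
  colnames(fm) <- paste0("f", seq_len(ncol(fm)))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids, group = unname(groups[ids])),
    tibble::as_tibble(fm))
  attr(out, "space") <- space
  attr(out, "metric") <- metric
  attr(out, "summary") <- summary
  class(out) <- c("feature_table", class(out))
  out
}

feature_matrix <- function(features) {
  as.matrix(features[, grep("^f\\d+$", names(features)), drop = FALSE])
}

#' Random-forest classification with repeated stratified splits
#'
#' Repeats a stratified subject-level 80/20 split `n_repeats` times; each
#' repeat fits a 1000-tree random forest on the training subjects and
#' scores the held-out subjects by out-of-split class probability, measured
#' as the area under the ROC curve (AUC). Splitting is at the subject
#' level, so no subject contributes to both sides of a split.
#'
#' @param features a `feature_table` (or tibble with `f*` columns).
#' @param labels two-level factor/vector, one label per row of `features`.
#' @param n_trees trees per forest (default 1000).
#' @param n_repeats number of random splits (default 10).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed; both the splits and the forests are seeded.
#' @return a `classification_report` tibble: repeat_id, auc; attributes
#'   carry the mean/SD and settings. See [glance.classification_report()].
#' @export
rf_classify <- function(features, labels, n_trees = 1000, n_repeats = 10,
                        train_frac = 0.8, seed = 1) {
  x <- feature_matrix(features)
  y <- factor(labels)
  abort_if(nlevels(y) != 2, "labels must have exactly two classes")
  abort_if(min(table(y)) < 2, "each class needs at least 2 subjects")
  pos <- levels(y)[2]
  aucs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, r))
    tr <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1, round(train_frac * length(idx))))
    }))
    te <- setdiff(seq_along(y), tr)
    if (length(unique(y[te])) < 2) {  # keep the held-out set two-class
      mv <- which(y == names(which.min(table(y[te]))) & seq_along(y) %in% tr)
      te <- c(te, mv[1])
      tr <- setdiff(tr, mv[1])
    }
    fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                          num.trees = n_trees, probability = TRUE,
                          seed = derive_seed(seed, 1000 + r),
                          num.threads = 1)
    prob <- predict(fit, data = x[te, , drop = FALSE],
                    num.threads = 1)$predictions[, pos]
    aucs[r] <- as.numeric(pROC::auc(response = y[te], predictor = prob,
                                    levels = levels(y), direction = "<",
                                    quiet = TRUE))
  }
  out <- tibble::tibble(repeat_id = seq_len(n_repeats), auc = aucs)
  attr(out, "auc_mean") <- mean(aucs)
  attr(out, "auc_sd") <- sd(aucs)
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  class(out) <- c("classification_report", class(out))
  out
}

#' @rdname rf_classify
#' @param x a `classification_report`.
#' @param ... unused.
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(auc_mean = attr(x, "auc_mean"), auc_sd = attr(x, "auc_sd"),
                 n_repeats = nrow(x), n_trees = attr(x, "n_trees"))
}

#' Welch two-sample comparison
#'
#' @param values_a,values_b numeric vectors (>= 2 each).
#' @return tibble: statistic (t), df, p.value, mean_a, mean_b.
#' @export
group_compare <- function(values_a, values_b) {
  abort_if(length(values_a) < 2 || length(values_b) < 2,
           "each group needs at least 2 values")
  abort_if(sd(values_a) == 0 && sd(values_b) == 0,
           "zero variance in both groups")
  tt <- t.test(values_a, values_b)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value,
                 mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Correlations between scalar dynamics metrics and behavioral domains
#'
#' For each of the four scalar metrics (mean FC and mean irreversibility,
#' in source and latent space) and each of the nine behavioral domains,
#' the Pearson correlation between the patients' metric values and their
#' domain scores -- the 1-year relative recovery by default, or the acute
#' (2-week) score.
#'
#' @param cohort a `bold_cohort`.
#' @param latent_model trained autoencoder for the latent metrics.
#' @param target `"recovery"` (relative change 2wk to 1yr) or `"acute"`.
#' @return a `behavior_correlations` tibble: metric, domain, r, p.value,
#'   plus a logical `best` flag marking each domain's strongest |r|.
#' @export
behavior_correlations <- function(cohort, latent_model,
                                  target = c("recovery", "acute")) {
  target <- match.arg(target)
  pats <- cohort$subjects$subject_id[cohort$subjects$group == "patient"]
  abort_if(length(pats) < 4, "need at least 4 patients")
  metrics <- list(
    fc_source = build_features(cohort, "source", "fc", "mean", subjects = pats),
    irrev_source = build_features(cohort, "source", "irreversibility", "mean",
                                  subjects = pats),
    fc_latent = build_features(cohort, "latent", "fc", "mean",
                               latent_model = latent_model, subjects = pats),
    irrev_latent = build_features(cohort, "latent", "irreversibility", "mean",
                                  latent_model = latent_model, subjects = pats))
  beh <- cohort$behavior[cohort$behavior$subject_id %in% pats, ]
  wide <- tidyr::pivot_wider(beh, names_from = "timepoint", values_from = "score")
  wide$target <- if (target == "recovery") {
    behavioral_recovery(wide$`2wk`, wide$`1yr`)
  } else wide$`2wk`
  rows <- list()
  for (mn in names(metrics)) {
    mt <- metrics[[mn]]
    mv <- setNames(mt$f1, mt$subject_id)
    for (dom in sort(unique(wide$domain))) {
      sub <- wide[wide$domain == dom, ]
      v <- mv[sub$subject_id]
      keep <- is.finite(v) & is.finite(sub$target)
      if (sum(keep) < 4 || sd(sub$target[keep]) == 0 || sd(v[keep]) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          metric = mn, domain = dom, r = NA_real_, p.value = NA_real_)
      } else {
        ct <- cor.test(v[keep], sub$target[keep])
        rows[[length(rows) + 1]] <- tibble::tibble(
          metric = mn, domain = dom, r = unname(ct$estimate),
          p.value = ct$p.value)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(dplyr::group_by(out, .data$domain),
                       best = !is.na(.data$r) &
                         abs(.data$r) == max(abs(.data$r), na.rm = TRUE))
  out <- dplyr::ungroup(out)
  class(out) <- c("behavior_correlations", class(out))
  out
}

#' 2-D t-SNE projection of a feature table
#'
#' Projects subjects into two dimensions with t-SNE (exact, seeded) for
#' visualisation of group separation; group centroids can be computed from
#' the returned tibble.
#'
#' @param features a `feature_table` (>= 5 subjects).
#' @param seed integer seed; fixed seed gives identical coordinates.
#' @param perplexity t-SNE perplexity; default adapts to the sample size.
#' @return tibble: subject_id, group, tsne1, tsne2.
#' @export
tsne_project <- function(features, seed = 1, perplexity = NULL) {
  x <- feature_matrix(features)
  n <- nrow(x)
  abort_if(n < 5, "need at least 5 subjects")
  perplexity <- perplexity %||% max(2, min(30, floor((n - 1) / 3)))
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, theta = 0,
                      check_duplicates = FALSE, pca = FALSE, max_iter = 500)
  tibble::tibble(subject_id = features$subject_id, group = features$group,
                 tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
}
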