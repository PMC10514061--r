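# experiment orchestration: preservation, classification, recovery

#' Pipeline configuration
#'
#' One validated key-value bundle driving all three experiments. Defaults
#' are the desk profile (50 regions x 400 frames, 30 controls + 60
#' patients) with analysis settings sized for a single CPU;
#' `profile = "full_scale"` switches the cohort geometry to 235 regions x
#' 896 frames. Unknown keys are rejected.
#'
#' @param ... overrides of any default listed below.
#' @param profile `"desk"` (default) or `"full_scale"`.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., profile = c("desk", "full_scale")) {
  profile <- match.arg(profile)
  cfg <- list(
    cohort = cohort_params(),
    seed = 1L,
    band = c(0.009, 0.08),
    apply_bandpass = FALSE,
    d_range = 2:8,
    latent_d = 6L,
    ae = ae_hyper(hidden = c(32, 16), max_epochs = 40, patience = 5),
    corr_threshold = 0.9,
    peak_n_iter = 200L,
    peak_p = 0.001,
    peak_z_max = 4.5,
    fcd_window = 30L,
    fcd_step = 3L,
    gamma_grid = seq(-0.3, 1, by = 0.1),
    louvain_restarts = 5L,
    complexity_bins = 20L,
    irrev_dt = 1L,
    rf_trees = 1000L,
    rf_repeats = 10L,
    rf_train_frac = 0.8)
  if (profile == "full_scale") {
    cfg$cohort <- cohort_params(n_roi = 235, n_frames = 896)
    cfg$ae <- ae_hyper(hidden = c(128, 64), max_epochs = 100, patience = 10)
    cfg$peak_n_iter <- 1000L
    cfg$gamma_grid <- seq(-0.3, 1, by = 0.05)
    cfg$louvain_restarts <- 20L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  abort_if(length(unknown) > 0,
           paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

pipeline_cohort <- function(config) {
  co <- generate_cohort(config$cohort, seed = config$seed)
  if (isTRUE(config$apply_bandpass)) {
    co$series <- lapply(co$series, bandpass,
                        low_hz = config$band[1], high_hz = config$band[2])
  }
  co
}

train_pipeline_ae <- function(cohort, config, d = NULL) {
  cat_frames <- concatenate_for_training(cohort, "acute")
  train_autoencoder(cat_frames$frames, d %||% config$latent_d,
                    hyper = config$ae, seed = derive_seed(config$seed, 77))
}

#' Feature-preservation experiment
#'
#' Generates (or accepts) a cohort, trains an autoencoder per bottleneck
#' dimension in `d_range`, computes the source-latent peak-agreement curve,
#' and compares the four dynamical features (pooled FCD distribution, edge
#' metastability, signed modularity Q, functional complexity) between
#' controls and patients in both spaces with Welch tests.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-generated `bold_cohort` (defaults to
#'   generating one from the config).
#' @return a `preservation_report`: list with `agreement` (an
#'   `agreement_curve`), `features` (per-subject tibble, both spaces),
#'   `comparisons` (tibble: space, feature, t, df, p), `embedding`
#'   (the per-d `embedding_report`), `config`.
#' @export
run_preservation_experiment <- function(config = pipeline_config(),
                                        cohort = NULL) {
  cohort <- cohort %||% pipeline_cohort(config)
  cat_frames <- concatenate_for_training(cohort, "acute")
  emb <- reconstruction_curve(cat_frames$frames, config$d_range,
                              hyper = config$ae,
                              seeds = derive_seed(config$seed, 77),
                              corr_threshold = config$corr_threshold)
  agree <- agreement_curve(cohort, emb$models, n_iter = config$peak_n_iter,
                           p = config$peak_p, z_max = config$peak_z_max,
                           seed = derive_seed(config$seed, 5))
  sel_d <- emb$selected_d
  if (is.na(sel_d)) sel_d <- config$latent_d
  model <- emb$models[[as.character(sel_d)]] %||%
    train_pipeline_ae(cohort, config, d = sel_d)
  fs <- list(
    source = dynamic_features(cohort, latent_model = NULL,
                              window_length = config$fcd_window,
                              window_step = config$fcd_step,
                              gamma_grid = config$gamma_grid,
                              n_restarts = config$louvain_restarts,
                              m = config$complexity_bins,
                              seed = derive_seed(config$seed, 6)),
    latent = dynamic_features(cohort, latent_model = model,
                              window_length = config$fcd_window,
                              window_step = config$fcd_step,
                              gamma_grid = config$gamma_grid,
                              n_restarts = config$louvain_restarts,
                              m = config$complexity_bins,
                              seed = derive_seed(config$seed, 7)))
  features <- dplyr::bind_rows(fs)
  comp <- list()
  for (sp in names(fs)) {
    f <- fs[[sp]]
    # the four preserved features; irreversibility stays in the per-subject
    # table but is compared in the classification experiment
    for (feat in c("fcd_mean", "metastability", "modularity_q", "complexity")) {
      gc_ <- group_compare(f[[feat]][f$group == "control"],
                           f[[feat]][f$group == "patient"])
      comp[[length(comp) + 1]] <- tibble::tibble(
        space = sp, feature = feat, statistic = gc_$statistic, df = gc_$df,
        p.value = gc_$p.value, mean_control = gc_$mean_a,
        mean_patient = gc_$mean_b)
    }
  }
  structure(list(agreement = agree, features = features,
                 comparisons = dplyr::bind_rows(comp), embedding = emb,
                 selected_d = sel_d, config = config),
            class = "preservation_report")
}

classification_grid <- function(cohort, model, labels_by_task, config,
                                subjects_by_task) {
  rows <- list()
  for (task in names(labels_by_task)) {
    subj <- subjects_by_task[[task]]
    labs <- labels_by_task[[task]]
    for (sp in c("source", "latent")) {
      for (mt in c("fc", "irreversibility")) {
        ft <- build_features(cohort, sp, mt, "upper_triangle",
                             latent_model = model, subjects = subj)
        ft <- ft[match(subj, ft$subject_id), ]
        rep_ <- rf_classify(ft, labs, n_trees = config$rf_trees,
                            n_repeats = config$rf_repeats,
                            train_frac = config$rf_train_frac,
                            seed = derive_seed(config$seed,
                                               match(task, names(labels_by_task)) * 100 +
                                                 match(sp, c("source", "latent")) * 10 +
                                                 match(mt, c("fc", "irreversibility"))))
        g <- glance(rep_)
        rows[[length(rows) + 1]] <- tibble::tibble(
          task = task, space = sp, metric = mt,
          auc_mean = g$auc_mean, auc_sd = g$auc_sd)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Acute-stage classification experiment
#'
#' Trains the autoencoder at the configured latent dimension and runs the
#' 2 x 2 feature grid (source/latent x mean-FC-matrix/irreversibility upper
#' triangles) on two acute label schemes: control vs patient, and
#' high vs low lesion volume within patients (median split). Also returns
#' the 2-D t-SNE projection of the latent irreversibility features and the
#' behavior-correlation table.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-generated cohort.
#' @return a `classification_report_set`: list with `auc` (8-row tibble:
#'   task x space x metric), `tsne` (coordinates), `behavior`
#'   (correlation table), `model`, `config`.
#' @export
run_classification_experiment <- function(config = pipeline_config(),
                                          cohort = NULL) {
  cohort <- cohort %||% pipeline_cohort(config)
  model <- train_pipeline_ae(cohort, config)
  subj <- cohort$subjects
  pats <- subj$subject_id[subj$group == "patient"]
  labels_by_task <- list(
    group = factor(subj$group, levels = c("control", "patient")),
    lesion = median_split(subj$lesion_volume[subj$group == "patient"]))
  subjects_by_task <- list(group = subj$subject_id, lesion = pats)
  auc <- classification_grid(cohort, model, labels_by_task, config,
                             subjects_by_task)
  ft_lat <- build_features(cohort, "latent", "irreversibility",
                           "upper_triangle", latent_model = model)
  tsne <- tsne_project(ft_lat, seed = derive_seed(config$seed, 9))
  beh <- behavior_correlations(cohort, model, target = "acute")
  structure(list(auc = auc, tsne = tsne, behavior = beh, model = model,
                 config = config),
            class = "classification_report_set")
}

#' Recovery-prediction experiment
#'
#' Longitudinal FC-distance and SC-FC-coupling trajectories for every
#' patient, the three median-split recovery label criteria (behavioral
#' domains recovered, 1-year FC distance, 1-year SC-FC coupling), their
#' pairwise chance-corrected agreement, and the 4 x 3 AUC grid predicting
#' each label set from acute features.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-generated cohort (patients must have 2wk and
#'   1yr series).
#' @return a `recovery_report`: list with `outcomes` (an `outcome_table`),
#'   `trajectories` (long tibble: subject_id, timepoint, fc_distance,
#'   sc_fc), `label_agreement` (pairwise kappa tibble), `auc` (12-row
#'   tibble), `model`, `config`.
#' @export
run_recovery_experiment <- function(config = pipeline_config(),
                                    cohort = NULL) {
  cohort <- cohort %||% pipeline_cohort(config)
  model <- train_pipeline_ae(cohort, config)
  out <- outcome_table(cohort)
  tps <- cohort$params$timepoints %||% c("2wk", "3mo", "1yr")
  traj <- dplyr::bind_rows(lapply(tps, function(tp) {
    tibble::tibble(subject_id = out$subject_id, timepoint = tp,
                   fc_distance = out[[paste0("fc_distance_", tp)]],
                   sc_fc = out[[paste0("sc_fc_", tp)]])
  }))
  crit <- list(behavior = out$label_behavior, fcdist = out$label_fcdist,
               scfc = out$label_scfc)
  pairs <- utils::combn(names(crit), 2)
  agree <- dplyr::bind_rows(apply(pairs, 2, function(pr) {
    k <- kappa_agreement(crit[[pr[1]]], crit[[pr[2]]])
    tibble::tibble(criterion_a = pr[1], criterion_b = pr[2],
                   kappa = k$kappa, p.value = k$p.value)
  }))
  auc <- classification_grid(cohort, model, crit, config,
                             stats::setNames(rep(list(out$subject_id),
                                                 length(crit)), names(crit)))
  structure(list(outcomes = out, trajectories = traj,
                 label_agreement = agree, auc = auc, model = model,
                 config = config),
            class = "recovery_report")
}
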