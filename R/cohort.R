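# synthetic stroke-like cohort generation and cohort I/O

#' Connectivity matrix container
#'
#' Tags a square symmetric matrix with the kind of connectivity it holds:
#' functional (`"FC"`), structural (`"SC"`) or an irreversibility matrix.
#'
#' @param m square numeric matrix.
#' @param kind one of `"FC"`, `"SC"`, `"irreversibility"`.
#' @return a `conn_matrix`.
#' @export
conn_matrix <- function(m, kind = c("FC", "SC", "irreversibility")) {
  kind <- match.arg(kind)
  abort_if(!is.matrix(m) || nrow(m) != ncol(m), "conn_matrix must be square")
  structure(m, kind = kind, class = "conn_matrix")
}

#' Full functional connectivity of a series
#'
#' Pearson correlation matrix across all frames.
#'
#' @param series a `subject_series` or matrix (regions x frames).
#' @return a `conn_matrix` of kind `"FC"`.
#' @export
fc_matrix <- function(series) {
  m <- as_series_matrix(series)
  conn_matrix(cor(t(m)), kind = "FC")
}

#' Cohort generation parameters
#'
#' Bundles every coefficient of the synthetic cohort generator with desk-scale
#' defaults (50 regions, 400 frames, 30 controls + 60 patients). The full
#' scale (235 regions x 896 frames) is a parameter choice, not a constant:
#' pass `n_roi = 235, n_frames = 896`.
#'
#' @param n_controls,n_patients group sizes (each >= 2).
#' @param n_roi,n_frames,tr series geometry; `tr` in seconds.
#' @param timepoints patient timepoints (controls get a single `"control"`
#'   series).
#' @param n_modules,within_w,between_w,homotopic_w,asymmetry,target_radius
#'   passed to [build_coupling()].
#' @param noise_sd,burn_in passed to [simulate_series()].
#' @param k_homotopic,k_asym lesion effect coefficients, see
#'   [lesion_coupling()].
#' @param lesion_frac lesion volume as a fraction of `n_roi` at severity 1.
#' @param nihss_scale NIHSS points at severity 1.
#' @param behavior_sd noise SD of behavioral domain scores.
#' @param beta_range range of the per-domain severity loading (uniform draw).
#' @return a named list of class `cohort_params`.
#' @export
cohort_params <- function(n_controls = 30, n_patients = 60, n_roi = 50,
                          n_frames = 400, tr = 2,
                          timepoints = c("2wk", "3mo", "1yr"),
                          n_modules = 2, within_w = 1, between_w = -0.1,
                          homotopic_w = 0.5, asymmetry = 0.05,
                          target_radius = 0.85, noise_sd = 1, burn_in = 100,
                          k_homotopic = 0.3, k_asym = 0.05,
                          lesion_frac = 0.15, nihss_scale = 20,
                          behavior_sd = 0.5, beta_range = c(1, 3)) {
  p <- as.list(environment())
  structure(p, class = "cohort_params")
}

timepoint_years <- c("2wk" = 14 / 365, "3mo" = 0.25, "1yr" = 1)

#' Generate a synthetic stroke-like cohort
#'
#' Simulates a control group and a patient group of VAR(1) BOLD-like series.
#' Patients carry a latent severity `s ~ Beta(2, 2)` and a recovery
#' rate drawn from `Gamma(shape 2, scale 0.5)` per year; severity at a timepoint `tau`
#' years post-stroke is `s * exp(-r * tau)`. The lesion reduces homotopic
#' coupling and adds temporal asymmetry in proportion to current severity
#' ([lesion_coupling()]), with the damaged-region set fixed per subject
#' across timepoints. Clinical covariates are severity-linked:
#' `lesion_volume = round(s * n_roi * lesion_frac)`,
#' `nihss = round(nihss_scale * s + N(0,1))` clipped at 0, and each of nine
#' behavioral domain scores at each timepoint is `-beta_d * s(tau) + noise`,
#' with `beta_d` drawn once per cohort. Controls have severity 0 throughout.
#'
#' All randomness flows from `seed` through a documented draw order
#' (coupling, domain loadings, patient covariates, behavior noise, then one
#' derived stream per series), so an identical seed reproduces the cohort
#' bit for bit.
#'
#' @param params a [cohort_params()] list.
#' @param seed integer master seed.
#' @return a `bold_cohort`: list with `subjects` (tibble), `behavior`
#'   (long tibble: subject_id, timepoint, domain, score), `series` (named
#'   list of `subject_series`), `sc_template` (`conn_matrix`, kind SC),
#'   `coupling` (the control `coupling_matrix`), `params`, `seed`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  abort_if(params$n_controls < 2 || params$n_patients < 2,
           "need at least 2 controls and 2 patients")
  p <- params
  base <- build_coupling(p$n_roi, p$n_modules, p$within_w, p$between_w,
                         p$homotopic_w, p$asymmetry, p$target_radius,
                         seed = derive_seed(seed, 1))

  set.seed(derive_seed(seed, 2))
  beta_d <- runif(9, p$beta_range[1], p$beta_range[2])
  sev <- rbeta(p$n_patients, 2, 2)
  rec <- rgamma(p$n_patients, shape = 2, scale = 0.5)
  nihss_noise <- rnorm(p$n_patients)

  ids_c <- sprintf("ctrl%03d", seq_len(p$n_controls))
  ids_p <- sprintf("pat%03d", seq_len(p$n_patients))
  subjects <- tibble::tibble(
    subject_id = c(ids_c, ids_p),
    group = rep(c("control", "patient"), c(p$n_controls, p$n_patients)),
    severity = c(rep(0, p$n_controls), sev),
    recovery_rate = c(rep(NA_real_, p$n_controls), rec),
    lesion_volume = c(rep(0L, p$n_controls),
                      as.integer(round(sev * p$n_roi * p$lesion_frac))),
    nihss = c(rep(0L, p$n_controls),
              pmax(0L, as.integer(round(p$nihss_scale * sev + nihss_noise)))))

  # behavior scores: controls at every patient timepoint with severity 0
  tps <- p$timepoints
  grid <- tidyr::expand_grid(subject_id = subjects$subject_id,
                             timepoint = tps, domain = sprintf("d%d", 1:9))
  grid <- dplyr::left_join(grid,
                           subjects[, c("subject_id", "severity", "recovery_rate")],
                           by = "subject_id")
  s_tau <- ifelse(grid$severity == 0, 0,
                  grid$severity * exp(-grid$recovery_rate *
                                        timepoint_years[grid$timepoint]))
  set.seed(derive_seed(seed, 3))
  noise <- rnorm(nrow(grid), sd = p$behavior_sd)
  b_idx <- as.integer(sub("^d", "", grid$domain))
  behavior <- tibble::tibble(subject_id = grid$subject_id,
                             timepoint = grid$timepoint,
                             domain = grid$domain,
                             score = -beta_d[b_idx] * s_tau + noise)

  series <- list()
  for (i in seq_len(p$n_controls)) {
    key <- paste0(ids_c[i], "_control")
    series[[key]] <- simulate_series(base, p$n_frames, p$noise_sd, p$burn_in,
                                     seed = derive_seed(seed, 100 + i),
                                     subject_id = ids_c[i],
                                     timepoint = "control", tr = p$tr)
  }
  for (i in seq_len(p$n_patients)) {
    n_les <- subjects$lesion_volume[p$n_controls + i]
    set.seed(derive_seed(seed, 5000 + i))
    les_set <- if (n_les > 0) sample.int(p$n_roi, n_les) else integer(0)
    for (j in seq_along(tps)) {
      s_tp <- sev[i] * exp(-rec[i] * timepoint_years[tps[j]])
      cp <- lesion_coupling(base, severity = s_tp,
                            k_homotopic = p$k_homotopic, k_asym = p$k_asym,
                            lesioned = les_set,
                            seed = derive_seed(seed, 10000 + i * 10 + j))
      key <- paste0(ids_p[i], "_", tps[j])
      series[[key]] <- simulate_series(cp, p$n_frames, p$noise_sd, p$burn_in,
                                       seed = derive_seed(seed, 20000 + i * 10 + j),
                                       subject_id = ids_p[i],
                                       timepoint = tps[j], tr = p$tr)
    }
  }

  sc <- abs((base$weights + t(base$weights)) / 2)
  diag(sc) <- 0
  structure(list(subjects = subjects, behavior = behavior, series = series,
                 sc_template = conn_matrix(sc, kind = "SC"),
                 coupling = base, params = p, seed = seed),
            class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("<bold_cohort> %d controls + %d patients, %d regions x %d frames, %d series\n",
              sum(x$subjects$group == "control"),
              sum(x$subjects$group == "patient"),
              x$params$n_roi, x$params$n_frames, length(x$series)))
  invisible(x)
}

# the acute series of one subject (controls: resting series)
acute_series <- function(cohort, subject_id) {
  g <- cohort$subjects$group[cohort$subjects$subject_id == subject_id]
  tp <- if (g == "control") "control" else "2wk"
  cohort$series[[paste0(subject_id, "_", tp)]]
}

#' Write / read a cohort as delimited text
#'
#' A cohort directory holds one `<subject>_<timepoint>.tsv` matrix per
#' series, a `cohort.tsv` metadata table (behavior scores in wide
#' `beh_<domain>_<timepoint>` columns), `sc_template.tsv`, and a
#' `params.json` sidecar echoing the generator parameters and seed.
#'
#' @param cohort a `bold_cohort`.
#' @param dir directory to create/read.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `bold_cohort` (without the generating `coupling`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$series)) {
    write_series(cohort$series[[key]], file.path(dir, paste0(key, ".tsv")))
  }
  wide <- tidyr::pivot_wider(cohort$behavior,
                             names_from = c("domain", "timepoint"),
                             values_from = "score",
                             names_glue = "beh_{domain}_{timepoint}")
  meta <- dplyr::left_join(cohort$subjects, wide, by = "subject_id")
  utils::write.table(meta, file.path(dir, "cohort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(unclass_matrix(cohort$sc_template),
                     file.path(dir, "sc_template.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  pj <- unclass(cohort$params)
  pj$seed <- cohort$seed
  jsonlite::write_json(pj, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

unclass_matrix <- function(m) { attributes(m) <- list(dim = dim(m)); m }

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  abort_if(!dir.exists(dir), paste0("no such cohort directory: ", dir))
  meta <- utils::read.table(file.path(dir, "cohort.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  beh_cols <- grep("^beh_", names(meta), value = TRUE)
  behavior <- tidyr::pivot_longer(
    tibble::as_tibble(meta[, c("subject_id", beh_cols)]),
    dplyr::all_of(beh_cols),
    names_to = c("domain", "timepoint"), names_pattern = "beh_(d\\d+)_(.+)",
    values_to = "score")
  subjects <- tibble::as_tibble(meta[, setdiff(names(meta), beh_cols)])
  files <- setdiff(list.files(dir, pattern = "\\.tsv$"),
                   c("cohort.tsv", "sc_template.tsv"))
  series <- list()
  for (f in files) {
    key <- sub("\\.tsv$", "", f)
    series[[key]] <- read_series(file.path(dir, f))
  }
  sc <- as.matrix(utils::read.table(file.path(dir, "sc_template.tsv"),
                                    sep = "\t", header = FALSE))
  dimnames(sc) <- NULL
  pj <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  seed <- pj$seed
  pj$seed <- NULL
  pj <- structure(pj, class = "cohort_params")
  structure(list(subjects = subjects, behavior = behavior, series = series,
                 sc_template = conn_matrix(sc, kind = "SC"),
                 coupling = NULL, params = pj, seed = seed),
            class = "bold_cohort")
}
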