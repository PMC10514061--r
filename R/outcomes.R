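# recovery-related outcome metrics and labelers

#' Frobenius distance between two connectivity matrices
#'
#' @param fc_subject,fc_reference square matrices of equal shape.
#' @return nonnegative scalar; 0 iff the matrices are identical.
#' @export
fc_distance <- function(fc_subject, fc_reference) {
  a <- if (inherits(fc_subject, "conn_matrix")) unclass_matrix(fc_subject) else fc_subject
  b <- if (inherits(fc_reference, "conn_matrix")) unclass_matrix(fc_reference) else fc_reference
  abort_if(!all(dim(a) == dim(b)), "shape mismatch between the two matrices")
  sqrt(sum((a - b)^2))
}

#' Average control FC matrix
#'
#' The elementwise mean functional connectivity of the control group, the
#' reference against which patient FC distances are measured.
#'
#' @param cohort a `bold_cohort`.
#' @return a `conn_matrix` of kind `"FC"`.
#' @export
reference_fc <- function(cohort) {
  ids <- cohort$subjects$subject_id[cohort$subjects$group == "control"]
  abort_if(length(ids) == 0, "cohort has no controls")
  mats <- lapply(ids, function(id) unclass_matrix(fc_matrix(acute_series(cohort, id))))
  conn_matrix(Reduce(`+`, mats) / length(mats), kind = "FC")
}

#' Structure-function coupling
#'
#' Pearson correlation between functional and structural connection
#' strengths over the region pairs with nonzero structural weight
#' (correlating against structural zeros would mostly measure sparsity).
#'
#' @param fc functional `conn_matrix` (or matrix).
#' @param sc structural `conn_matrix` (or matrix) of the same shape.
#' @return correlation in `[-1, 1]`.
#' @export
sc_fc_coupling <- function(fc, sc) {
  f <- if (inherits(fc, "conn_matrix")) unclass_matrix(fc) else fc
  s <- if (inherits(sc, "conn_matrix")) unclass_matrix(sc) else sc
  abort_if(!all(dim(f) == dim(s)), "shape mismatch between FC and SC")
  fu <- upper_tri(f)
  su <- upper_tri(s)
  mask <- su > 0
  abort_if(sum(mask) < 2 || sd(su[mask]) == 0 || sd(fu[mask]) == 0,
           "degenerate structural mask: need >= 2 distinct nonzero SC values")
  cor(fu[mask], su[mask])
}

#' Behavioral recovery of one domain score
#'
#' Relative change from the 2-week to the 1-year score:
#' `(score_1yr - score_2wk) / score_2wk`. With z-scored deficit scores the
#' baseline is typically negative, so a deficit moving toward 0 yields a
#' negative ratio (e.g. -2 to -1 gives -0.5); interpret magnitudes with the
#' baseline sign in mind. A zero baseline leaves the ratio undefined (`NA`),
#' not an error.
#'
#' @param score_2wk,score_1yr domain scores at the two timepoints.
#' @return the relative change, or `NA` for a zero baseline.
#' @export
behavioral_recovery <- function(score_2wk, score_1yr) {
  ifelse(score_2wk == 0, NA_real_, (score_1yr - score_2wk) / score_2wk)
}

#' Count of behavioral domains recovered after one year
#'
#' Two explicit readings of "recovered" are provided. The default,
#' `"normalized"`, counts a domain as recovered when its 1-year score lies
#' within the normal range (|score| below `threshold`; domain scores are
#' z-scored against controls, so the default threshold of 1 is twice the
#' nominal control noise SD) -- recovery as a state reached by 1 year.
#' `"improvement"` instead counts a domain whose deficit magnitude
#' decreased by more than `margin` between 2 weeks and 1 year -- recovery
#' as a change. The state reading is the default because it is the one
#' under which the three recovery criteria (behavior, FC distance, SC-FC
#' coupling) measure the same construct, the residual deficit at 1 year.
#'
#' @param behavior long behavior tibble (subject_id, timepoint, domain,
#'   score) for one or more subjects.
#' @param rule `"normalized"` (default) or `"improvement"`.
#' @param threshold normal-range half-width for the `"normalized"` rule.
#' @param margin minimal magnitude decrease for the `"improvement"` rule
#'   (default 0: any improvement).
#' @return tibble: subject_id, domains_recovered (0..9).
#' @export
domains_recovered <- function(behavior, rule = c("normalized", "improvement"),
                              threshold = 1, margin = 0) {
  rule <- match.arg(rule)
  wide <- tidyr::pivot_wider(behavior[behavior$timepoint %in% c("2wk", "1yr"), ],
                             names_from = "timepoint", values_from = "score")
  abort_if(!all(c("2wk", "1yr") %in% names(wide)),
           "behavior table must contain both 2wk and 1yr scores")
  wide$recovered <- if (rule == "normalized") {
    abs(wide$`1yr`) < threshold
  } else {
    abs(wide$`1yr`) < abs(wide$`2wk`) - margin
  }
  dplyr::summarise(dplyr::group_by(wide, .data$subject_id),
                   domains_recovered = sum(.data$recovered, na.rm = TRUE),
                   .groups = "drop")
}

#' Median split into high/low labels
#'
#' Values above the median become `"high"`, below become `"low"`. Values
#' equal to the median are assigned to `"low"` in stable input order until
#' the low group reaches `ceiling(n/2)`, then to `"high"`, so the label
#' counts never differ by more than one.
#'
#' @param values numeric vector, length >= 4, not all identical.
#' @return factor of `"low"`/`"high"` labels in input order.
#' @export
median_split <- function(values) {
  abort_if(length(values) < 4, "need at least 4 values to split")
  abort_if(length(unique(values)) == 1,
           "all values identical: median split undefined")
  med <- median(values)
  lab <- ifelse(values > med, "high", ifelse(values < med, "low", NA))
  ties <- which(is.na(lab))
  if (length(ties)) {
    need_low <- max(0L, ceiling(length(values) / 2) - sum(lab == "low", na.rm = TRUE))
    lab[ties] <- c(rep("low", min(need_low, length(ties))),
                   rep("high", max(0L, length(ties) - need_low)))
  }
  factor(lab, levels = c("low", "high"))
}

#' Per-patient outcome table
#'
#' Longitudinal FC distance to the control reference and SC-FC coupling at
#' every patient timepoint, the behavioral domain-recovery count, and the
#' three high/low recovery labels (behavior count; FC distance at 1 year,
#' lower distance = better recovery; SC-FC coupling at 1 year, higher =
#' better).
#'
#' @param cohort a `bold_cohort` whose patients have 2wk and 1yr series.
#' @return an `outcome_table` tibble: subject_id, fc_distance and
#'   sc_fc_coupling per timepoint (wide columns), domains_recovered, and
#'   label_behavior / label_fcdist / label_scfc factors.
#' @export
outcome_table <- function(cohort) {
  pats <- cohort$subjects$subject_id[cohort$subjects$group == "patient"]
  abort_if(length(pats) < 4, "need at least 4 patients")
  ref <- reference_fc(cohort)
  tps <- cohort$params$timepoints %||% c("2wk", "3mo", "1yr")
  rows <- lapply(pats, function(id) {
    vals <- lapply(tps, function(tp) {
      s <- cohort$series[[paste0(id, "_", tp)]]
      abort_if(is.null(s), sprintf("missing series for %s at %s", id, tp))
      fc <- fc_matrix(s)
      c(fc_distance(fc, ref), sc_fc_coupling(fc, cohort$sc_template))
    })
    out <- tibble::tibble(subject_id = id)
    for (i in seq_along(tps)) {
      out[[paste0("fc_distance_", tps[i])]] <- vals[[i]][1]
      out[[paste0("sc_fc_", tps[i])]] <- vals[[i]][2]
    }
    out
  })
  tab <- dplyr::bind_rows(rows)
  beh <- cohort$behavior[cohort$behavior$subject_id %in% pats, ]
  tab <- dplyr::left_join(tab, domains_recovered(beh), by = "subject_id")
  tab$label_behavior <- median_split(tab$domains_recovered)
  tab$label_fcdist <- median_split(-tab$fc_distance_1yr)  # low distance = high recovery
  tab$label_scfc <- median_split(tab$sc_fc_1yr)
  class(tab) <- c("outcome_table", class(tab))
  tab
}

#' Cohen's kappa agreement between two label vectors
#'
#' Chance-corrected agreement, with a Fisher exact association p-value as
#' the above-chance test.
#'
#' @param a,b factors or vectors of equal length with two levels.
#' @return tibble: kappa, p.value.
#' @export
kappa_agreement <- function(a, b) {
  abort_if(length(a) != length(b), "label vectors differ in length")
  tab <- table(a, b)
  po <- sum(diag(tab)) / sum(tab)
  pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
  k <- (po - pe) / (1 - pe)
  p <- fisher.test(tab)$p.value
  tibble::tibble(kappa = k, p.value = p)
}
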