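#' Frontal alpha asymmetry from an F4/F3 alpha-power pair
#'
#' FAA is the log power difference between the right and left frontal
#' electrodes: `ln(F4) - ln(F3)`. Lower (more negative) values indicate
#' relatively greater right-frontal cortical activity, because alpha power
#' is inversely related to cortical activation.
#'
#' @param alpha_f4,alpha_f3 Alpha-band power at F4 and F3 (uV^2, > 0);
#'   vectorised.
#' @return The FAA ln-ratio.
#' @export
#' @examples
#' compute_faa(2, 1)   # log(2)
compute_faa <- function(alpha_f4, alpha_f3) {
  if (any(alpha_f4 <= 0) || any(alpha_f3 <= 0)) {
    abort("Alpha powers must be > 0.")
  }
  log(alpha_f4) - log(alpha_f3)
}

#' Emotional modulation of FAA
#'
#' eFAA isolates the impact of threat-related emotional content on frontal
#' alpha asymmetry: FAA in the threat condition minus FAA in the
#' emotionally neutral condition.
#'
#' @param faa_threat,faa_neutral FAA ln-ratios in the threat and neutral
#'   conditions; vectorised.
#' @return The eFAA ln-ratio.
#' @export
#' @examples
#' compute_efaa(-0.194, -0.215)
compute_efaa <- function(faa_threat, faa_neutral) {
  if (any(!is.finite(faa_threat)) || any(!is.finite(faa_neutral))) {
    abort("FAA inputs must be finite.")
  }
  faa_threat - faa_neutral
}

#' Outlier bounds from a mean/SD rule
#'
#' The outlier rule flags values outside `mean +/- k * SD`. `outlier_rule()`
#' builds the rule from a given centre and spread; `outlier_bounds()`
#' estimates them from pooled data (arithmetic mean, sample SD with the
#' n - 1 denominator).
#'
#' @param center,spread Centre (mean) and spread (SD) of the rule.
#' @param k Multiplier (default 2.5).
#' @return A list of class `outlier_rule` with `center`, `spread`, `k`,
#'   `lower`, `upper`.
#' @export
#' @examples
#' outlier_rule(-0.14, 0.41)    # bounds (-1.165, 0.885)
outlier_rule <- function(center, spread, k = 2.5) {
  assert_scalar_number(center, "center")
  assert_scalar_number(spread, "spread")
  if (spread < 0) abort("`spread` must be >= 0.")
  structure(
    list(center = center, spread = spread, k = k,
         lower = center - k * spread, upper = center + k * spread),
    class = "outlier_rule"
  )
}

#' @rdname outlier_rule
#' @param values Numeric vector (length >= 2) to pool.
#' @export
outlier_bounds <- function(values, k = 2.5) {
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("Need at least 2 finite values.")
  outlier_rule(mean(values), sd(values), k)
}

#' @export
print.outlier_rule <- function(x, ...) {
  cat(sprintf(
    "<outlier_rule> mean %.4g +/- %.1f x SD %.4g -> (%.4g, %.4g)\n",
    x$center, x$k, x$spread, x$lower, x$upper
  ))
  invisible(x)
}

#' Remove subjects outside the pooled outlier bounds
#'
#' Applies the mean +/- k SD rule to one score column, pooling all groups
#' for the bounds, in a single pass (bounds are not re-estimated after
#' removal). Only strict exceedance removes: a value exactly at a bound is
#' kept. Removed ids and values are reported.
#'
#' @param scores Tibble with a `subject_id` column.
#' @param field Name of the score column (e.g. "faa_overall" or "efaa").
#' @param k Multiplier (default 2.5).
#' @return A list with `kept` and `removed` tibbles and the `rule` used.
#' @export
remove_outliers <- function(scores, field, k = 2.5) {
  if (!field %in% names(scores)) {
    abort(sprintf("Column `%s` not present in `scores`.", field))
  }
  v <- scores[[field]]
  rule <- outlier_bounds(v, k)
  out <- v < rule$lower | v > rule$upper
  out[is.na(out)] <- FALSE
  if (any(out)) {
    inform(sprintf(
      "Removed %d outlier(s) on %s: %s",
      sum(out), field,
      paste(sprintf("%s (%.3f)", scores$subject_id[out], v[out]),
            collapse = ", ")
    ))
  }
  list(kept = scores[!out, ], removed = scores[out, ], rule = rule)
}

#' Subject-level FAA and eFAA scores from an alpha-power table
#'
#' Computes, per subject: FAA in each emotion x relevance cell
#' (`ln(F4) - ln(F3)` of the cell-mean alpha AUC), FAA per emotion (mean
#' over relevance), overall FAA (unweighted mean of the four cells), eFAA
#' per relevance (threat minus neutral at that relevance), and the scalar
#' eFAA (mean of the two). Subjects with any required cell missing are
#' excluded and reported. Questionnaire covariates are joined when a
#' scores table is given.
#'
#' @param alpha_table Output of [condition_alpha_table()] (rows for F3 and
#'   F4), possibly row-bound over subjects.
#' @param scores Optional questionnaire [read_scores()] table to join.
#' @return A tibble, one row per subject, of class `faa_scores`: columns
#'   `subject_id`, `group` (if joined), `faa_<emotion>_<relevance>`,
#'   `faa_threat`, `faa_neutral`, `faa_overall`, `efaa_relevant`,
#'   `efaa_irrelevant`, `efaa`, plus covariates.
#' @export
subject_scores <- function(alpha_table, scores = NULL) {
  need <- c("subject", "electrode", "emotion", "relevance", "auc")
  if (!all(need %in% names(alpha_table))) {
    abort("`alpha_table` must come from condition_alpha_table().")
  }
  if ("missing" %in% names(alpha_table)) {
    bad <- unique(alpha_table$subject[alpha_table$missing])
    if (length(bad) > 0) {
      inform(sprintf(
        "Excluding %d subject(s) with missing condition cells: %s",
        length(bad), paste(bad, collapse = ", ")
      ))
      alpha_table <- alpha_table[!alpha_table$subject %in% bad, ]
    }
  }
  if (nrow(alpha_table) == 0) abort("No complete subjects in `alpha_table`.")

  wide <- tidyr::pivot_wider(
    dplyr::select(alpha_table, "subject", "electrode", "emotion",
                  "relevance", "auc"),
    names_from = "electrode", values_from = "auc"
  )
  wide$faa <- compute_faa(wide$F4, wide$F3)
  cells <- tidyr::pivot_wider(
    dplyr::select(wide, "subject", "emotion", "relevance", "faa"),
    names_from = c("emotion", "relevance"), values_from = "faa",
    names_prefix = "faa_"
  )
  out <- dplyr::mutate(cells,
    faa_threat = (.data$faa_threat_relevant + .data$faa_threat_irrelevant) / 2,
    faa_neutral = (.data$faa_neutral_relevant + .data$faa_neutral_irrelevant) / 2,
    faa_overall = (.data$faa_threat + .data$faa_neutral) / 2,
    efaa_relevant = compute_efaa(.data$faa_threat_relevant,
                                 .data$faa_neutral_relevant),
    efaa_irrelevant = compute_efaa(.data$faa_threat_irrelevant,
                                   .data$faa_neutral_irrelevant),
    efaa = (.data$efaa_relevant + .data$efaa_irrelevant) / 2
  )
  out <- dplyr::rename(out, subject_id = "subject")
  if (!is.null(scores)) {
    out <- dplyr::left_join(out, scores, by = "subject_id")
  }
  class(out) <- c("faa_scores", class(out))
  out
}

#' Group-summary table of FAA, eFAA and alpha power
#'
#' Produces the group x emotion summary: mean and SD of F4 power, F3
#' power, ln(F4), ln(F3) and FAA per group and emotion condition, and
#' per-group mean/SD of eFAA and overall FAA. Because the tabulated FAA is
#' the subject-mean of `lnF4 - lnF3`, the identity `FAA mean = mean(lnF4)
#' - mean(lnF3)` holds exactly, as does `eFAA mean = FAA(threat) mean -
#' FAA(neutral) mean`; both are asserted on every produced table.
#' Single-subject groups pass means through with `NA` SDs.
#'
#' @param alpha_table Row-bound [condition_alpha_table()] rows for all
#'   subjects (F3 and F4).
#' @param groups Tibble with `subject_id` and `group` columns.
#' @return A tibble shaped like the published summary: one row per group x
#'   emotion with power, ln-power, FAA and eFAA columns.
#' @export
group_summary_table <- function(alpha_table, groups) {
  subj <- subject_scores(alpha_table)
  subj <- dplyr::inner_join(subj, groups, by = "subject_id")
  if (nrow(subj) == 0) abort("No subjects with group labels.")

  pow <- dplyr::summarise(
    dplyr::group_by(
      dplyr::inner_join(alpha_table, groups, by = c(subject = "subject_id")),
      .data$group, .data$emotion, .data$electrode
    ),
    power = mean(.data$auc), power_sd = sd(.data$auc),
    ln = mean(log(.data$auc)), ln_sd = sd(log(.data$auc)),
    .groups = "drop"
  )
  pow_wide <- tidyr::pivot_wider(pow,
    names_from = "electrode",
    values_from = c("power", "power_sd", "ln", "ln_sd")
  )

  faa_long <- tidyr::pivot_longer(
    dplyr::select(subj, "subject_id", "group", "faa_threat", "faa_neutral"),
    cols = c("faa_threat", "faa_neutral"),
    names_to = "emotion", names_prefix = "faa_", values_to = "faa"
  )
  faa_sum <- dplyr::summarise(
    dplyr::group_by(faa_long, .data$group, .data$emotion),
    faa_sd = sd(.data$faa), faa = mean(.data$faa), .groups = "drop"
  )
  gsum <- dplyr::summarise(
    dplyr::group_by(subj, .data$group),
    efaa_sd = sd(.data$efaa), efaa = mean(.data$efaa),
    faa_overall_sd = sd(.data$faa_overall),
    faa_overall = mean(.data$faa_overall),
    n = dplyr::n(), .groups = "drop"
  )

  out <- dplyr::left_join(faa_sum, pow_wide, by = c("group", "emotion"))
  out <- dplyr::left_join(out, gsum, by = "group")
  out <- dplyr::arrange(out, .data$group, .data$emotion)

  # linearity identities: mean of differences = difference of means
  subj_ln <- dplyr::summarise(
    dplyr::group_by(
      dplyr::inner_join(alpha_table, groups, by = c(subject = "subject_id")),
      .data$group, .data$emotion, .data$electrode, .data$subject
    ),
    ln_cellmean = mean(log(.data$auc)), .groups = "drop"
  )
  chk <- tidyr::pivot_wider(subj_ln, names_from = "electrode",
                            values_from = "ln_cellmean")
  chk <- dplyr::summarise(
    dplyr::group_by(chk, .data$group, .data$emotion),
    faa_from_ln = mean(.data$F4) - mean(.data$F3), .groups = "drop"
  )
  chk <- dplyr::inner_join(chk, faa_sum, by = c("group", "emotion"))
  # identical only when per-cell ln power equals ln of the cell-mean AUC per
  # subject, which subject_scores guarantees by construction
  stopifnot(max(abs(chk$faa_from_ln - chk$faa)) < 1e-10)
  efaa_chk <- tidyr::pivot_wider(faa_sum[, c("group", "emotion", "faa")],
                                 names_from = "emotion", values_from = "faa")
  efaa_chk <- dplyr::inner_join(efaa_chk, gsum[, c("group", "efaa")],
                                by = "group")
  stopifnot(max(abs((efaa_chk$threat - efaa_chk$neutral) - efaa_chk$efaa)) < 1e-10)

  out
}
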