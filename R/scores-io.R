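#' Read or write the per-subject scores table
#'
#' The scores table holds one row per subject: group membership,
#' questionnaire totals (RPQ, RPQ-Emotional, BDI, BRIEF GEC, BRIEF
#' Emotional Control), age, and the clinical covariates available for
#' mild-TBI subjects only (post-traumatic amnesia in hours, months from
#' injury to recording). Files are RFC-4180 CSV with a fixed header,
#' "." decimal separator, and empty fields for missing clinical values.
#' Readers validate rather than coerce: unknown group labels, duplicate
#' subject ids and clinical values on control rows are errors.
#'
#' @param scores Tibble as produced by [generate_questionnaires()].
#' @param path CSV file path.
#' @return `read_scores()` returns the validated tibble; `write_scores()`
#'   invisibly returns `path`.
#' @export
write_scores <- function(scores, path) {
  validate_scores(scores)
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort(sprintf("Scores file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df <- as_tibble(df)
  int_cols <- c("rpq", "rpq_emotional", "bdi", "brief_gec", "brief_ec", "age")
  for (cl in intersect(int_cols, names(df))) df[[cl]] <- as.integer(df[[cl]])
  validate_scores(df)
  df
}

scores_columns <- function() {
  c("subject_id", "group", "rpq", "rpq_emotional", "bdi", "brief_gec",
    "brief_ec", "age", "pta_hours", "months_post_injury")
}

validate_scores <- function(scores) {
  missing_cols <- setdiff(scores_columns(), names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("Scores table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- scores$subject_id[duplicated(scores$subject_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate subject id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(unique(scores$group), c("Control", "NonSymp", "Symp"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown group label(s): %s", paste(bad, collapse = ", ")))
  }
  ctrl <- scores$group == "Control"
  if (any(ctrl & (!is.na(scores$pta_hours) | !is.na(scores$months_post_injury)))) {
    abort("Control subjects must have empty PTA and months_post_injury.")
  }
  if (any(!ctrl & (is.na(scores$pta_hours) | is.na(scores$months_post_injury)))) {
    abort("Mild-TBI subjects must have PTA and months_post_injury.")
  }
  if (any(scores$group == "NonSymp" & scores$rpq != 0L)) {
    abort("NonSymp subjects must have RPQ total 0.")
  }
  if (any(scores$group == "Symp" & scores$rpq < 1L)) {
    abort("Symp subjects must have RPQ total >= 1.")
  }
  if (any(scores$rpq_emotional > scores$rpq)) {
    abort("RPQ-Emotional cannot exceed the RPQ total.")
  }
  invisible(scores)
}
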