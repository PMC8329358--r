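#' Generate a complete synthetic cohort
#'
#' Draws the latent subject layer ([simulate_subject_scores()]), synthesises
#' one continuous EEG recording per subject ([synthesize_recording()]) over
#' a shared task-event plan, and generates coupled questionnaire scores
#' ([generate_questionnaires()]). The ground-truth table stores each
#' subject's realised per-cell FAA targets and latent eFAA for
#' parameter-recovery checks. Everything derives deterministically from the
#' master seed in the spec.
#'
#' @param spec A [cohort_spec()].
#' @param keep_recordings If `FALSE`, recordings are not accumulated in
#'   memory and `recordings` is `NULL` (use [simulate_cohort_files()] to
#'   stream them to disk instead).
#' @return A list with elements `recordings` (named list of
#'   [eeg_recording()]s), `events` (the shared task plan), `scores`
#'   (questionnaire table), `ground_truth` (tibble: subject x cell realised
#'   FAA and latent eFAA), and `spec`.
#' @export
generate_cohort <- function(spec, keep_recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  latent <- simulate_subject_scores(spec, seed = spec$seed)
  events <- generate_task_events(
    seed = spec$seed + 1L,
    n_blocks = spec$n_blocks,
    trials_per_block = spec$trials_per_block,
    iti_range = spec$iti_range
  )
  subjects <- dplyr::distinct(latent, .data$subject_id, .data$group,
    .data$efaa_latent)
  scores <- generate_questionnaires(
    setNames(subjects$efaa_latent, subjects$subject_id),
    subjects$group, spec,
    seed = spec$seed + 2L
  )

  recordings <- NULL
  if (keep_recordings) {
    recordings <- purrr::imap(
      split(latent, latent$subject_id)[subjects$subject_id],
      function(cells, sid) {
        synthesize_recording(
          cells, events, spec,
          seed = spec$seed + 1000L + match(sid, subjects$subject_id)
        )
      }
    )
  }

  list(
    recordings = recordings,
    events = events,
    scores = scores,
    ground_truth = latent,
    spec = spec
  )
}
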