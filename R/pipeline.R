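#' Simulate a cohort to disk as BrainVision files plus CSV sidecars
#'
#' Streams one BrainVision triplet per subject into `out_dir`, together
#' with `scores.csv` (questionnaires), `ground_truth.csv` (realised
#' per-cell FAA targets and latent eFAA) and a `manifest.json` recording
#' the seed, group sizes and package version. Outputs are a deterministic
#' function of the spec's master seed.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory (default FALSE).
#' @return Invisibly, a tibble mapping `subject_id` to the written `.vhdr`.
#' @export
simulate_cohort_files <- function(spec, out_dir, force = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    abort(sprintf("Output directory %s is not empty (use force = TRUE).",
                  out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  latent <- simulate_subject_scores(spec, seed = spec$seed)
  events <- generate_task_events(
    seed = spec$seed + 1L, n_blocks = spec$n_blocks,
    trials_per_block = spec$trials_per_block, iti_range = spec$iti_range
  )
  subjects <- dplyr::distinct(latent, .data$subject_id, .data$group,
                              .data$efaa_latent)
  scores <- generate_questionnaires(
    setNames(subjects$efaa_latent, subjects$subject_id),
    subjects$group, spec, seed = spec$seed + 2L
  )
  write_scores(scores, file.path(out_dir, "scores.csv"))
  utils::write.csv(latent, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE, na = "")

  files <- purrr::map_chr(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    rec <- synthesize_recording(
      latent[latent$subject_id == sid, ], events, spec,
      seed = spec$seed + 1000L + i
    )
    base <- file.path(out_dir, sid)
    write_brainvision(rec, base)
    paste0(base, ".vhdr")
  })

  jsonlite::write_json(
    list(
      seed = spec$seed,
      n = as.list(spec$n),
      n_blocks = spec$n_blocks,
      trials_per_block = spec$trials_per_block,
      package_version = as.character(utils::packageVersion("efaa")),
      subjects = subjects$subject_id
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(tibble(subject_id = subjects$subject_id, vhdr = files))
}

#' Analyse a directory of per-subject recordings end to end
#'
#' Runs the whole chain on a simulated (or schema-compatible) data
#' directory: read each BrainVision triplet, preprocess
#' ([preprocess_recording()]), tabulate alpha power
#' ([condition_alpha_table()]), build subject scores, the group summary
#' table and the full inference battery. When `out_dir` is given, the
#' alpha table, subject scores, group summary and inference JSON are
#' written there.
#'
#' @param data_dir Directory produced by [simulate_cohort_files()].
#' @param out_dir Optional output directory for result files.
#' @param ocular "regression" (default) or "none".
#' @param reject_limit Artifact threshold in uV (default 80).
#' @param min_segments Minimum segments per condition cell (default 10).
#' @param outlier_k Outlier-rule multiplier (default 2.5).
#' @return A list: `alpha_table`, `scores` (subject-level FAA/eFAA with
#'   covariates), `summary` (group summary table), `inference`
#'   (`faa_inference`).
#' @export
analyze_cohort <- function(data_dir, out_dir = NULL,
                           ocular = "regression", reject_limit = 80,
                           min_segments = 10, outlier_k = 2.5) {
  scores_path <- file.path(data_dir, "scores.csv")
  if (!file.exists(scores_path)) {
    abort(sprintf("No scores.csv in %s.", data_dir))
  }
  questionnaires <- read_scores(scores_path)
  vhdrs <- sort(list.files(data_dir, pattern = "\\.vhdr$", full.names = TRUE))
  if (length(vhdrs) == 0) abort(sprintf("No .vhdr files in %s.", data_dir))

  alpha_table <- purrr::map_dfr(vhdrs, function(f) {
    rec <- read_brainvision(f)
    segs <- preprocess_recording(rec, ocular = ocular,
                                 reject_limit = reject_limit)
    condition_alpha_table(
      segs, min_segments = min_segments,
      subject_id = sub("\\.vhdr$", "", basename(f))
    )
  })

  scores <- subject_scores(alpha_table, questionnaires)
  groups <- dplyr::select(questionnaires, "subject_id", "group")
  summary_tbl <- group_summary_table(alpha_table, groups)
  inference <- run_full_inference(scores, outlier_k = outlier_k)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(alpha_table, file.path(out_dir, "alpha_power.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(scores, file.path(out_dir, "subject_scores.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(summary_tbl, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE, na = "")
    write_inference_json(inference, file.path(out_dir, "inference.json"))
  }
  list(alpha_table = alpha_table, scores = scores, summary = summary_tbl,
       inference = inference)
}
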