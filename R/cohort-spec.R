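#' Specification of a synthetic FAA cohort
#'
#' Collects every parameter of the synthetic cohort generator: group sizes,
#' per-group per-condition target FAA (the four emotion x relevance cells),
#' the signal model (base alpha power at F3, alpha peak frequency, pink-noise
#' level, blink rate/amplitude/propagation), between-subject variability, and
#' the questionnaire coupling targets (Spearman rho between the latent eFAA
#' and BDI, RPQ, PTA). The defaults reproduce the reference study
#' conditions: group sizes 17/12/15 and group-level FAA/eFAA equal to the
#' published group summary ([reference_group_summary()]), with the same
#' target FAA in the relevant and irrelevant cells (the reference summary
#' does not split by relevance).
#'
#' @param n_control,n_nonsymp,n_symp Group sizes (default 17, 12, 15).
#' @param cell_faa Tibble with columns `group`, `emotion`, `relevance`,
#'   `faa`: target group-mean FAA per cell. Default: published group means,
#'   duplicated across relevance.
#' @param sd_faa Between-subject SD of the subject's overall FAA offset
#'   (ln-ratio; default 0.30, the scale of the published per-group FAA SDs).
#' @param sd_efaa Between-subject SD of the subject's emotional-modulation
#'   offset (default 0.034, the scale of the published eFAA SDs).
#' @param base_power_f3 Alpha-band power at F3 in uV^2 (default 5, the scale
#'   of the published power values).
#' @param alpha_freq Alpha peak frequency in Hz (default 10).
#' @param noise_rms Pink-noise RMS in uV (default 2).
#' @param blink_rate Blink rate in events per minute (default 12).
#' @param blink_amplitude Blink amplitude on the VEOG channel in uV
#'   (default 500; must exceed 80 so that uncorrected blinks trigger the
#'   amplitude rejection rule on frontal channels at the default
#'   propagation).
#' @param blink_propagation Fraction of the VEOG blink reaching frontal EEG
#'   channels (default 0.3).
#' @param rho_bdi,rho_rpq,rho_pta Target Spearman correlations between latent
#'   eFAA and BDI (all subjects), RPQ (all subjects), PTA (mild-TBI subjects
#'   only). Defaults -0.52, -0.34, +0.41.
#' @param n_blocks,trials_per_block,iti_range Task structure passed to
#'   [generate_task_events()] (defaults 16 blocks of 64 trials, ITI
#'   2.5–3.5 s).
#' @param seed Master seed (default 1); every random stream derives from it.
#'
#' @return An object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_control = 17L, n_nonsymp = 12L, n_symp = 15L,
                        cell_faa = default_cell_faa(),
                        sd_faa = 0.30, sd_efaa = 0.034,
                        base_power_f3 = 5, alpha_freq = 10,
                        noise_rms = 2,
                        blink_rate = 12, blink_amplitude = 500,
                        blink_propagation = 0.3,
                        rho_bdi = -0.52, rho_rpq = -0.34, rho_pta = 0.41,
                        n_blocks = 16L, trials_per_block = 64L,
                        iti_range = c(2.5, 3.5),
                        seed = 1L) {
  for (n in c(n_control, n_nonsymp, n_symp)) {
    if (n < 1) abort("Group sizes must be >= 1.")
  }
  assert_scalar_number(base_power_f3, "base_power_f3", positive = TRUE)
  assert_scalar_number(alpha_freq, "alpha_freq", positive = TRUE)
  if (blink_rate > 0 && blink_amplitude <= 80) {
    abort("`blink_amplitude` must exceed 80 uV so blinks are rejectable.")
  }
  for (r in c(rho_bdi, rho_rpq, rho_pta)) {
    if (abs(r) >= 1) abort("Coupling rhos must have magnitude < 1.")
  }
  req <- tidyr::expand_grid(
    group = c("Control", "NonSymp", "Symp"),
    emotion = c("neutral", "threat"),
    relevance = c("irrelevant", "relevant")
  )
  chk <- dplyr::anti_join(req, cell_faa,
    by = c("group", "emotion", "relevance")
  )
  if (nrow(chk) > 0) abort("`cell_faa` must cover all 12 group x emotion x relevance cells.")

  structure(
    list(
      n = c(Control = as.integer(n_control), NonSymp = as.integer(n_nonsymp),
            Symp = as.integer(n_symp)),
      cell_faa = cell_faa,
      sd_faa = sd_faa, sd_efaa = sd_efaa,
      base_power_f3 = base_power_f3, alpha_freq = alpha_freq,
      noise_rms = noise_rms,
      blink_rate = blink_rate, blink_amplitude = blink_amplitude,
      blink_propagation = blink_propagation,
      rho = c(bdi = rho_bdi, rpq = rho_rpq, pta = rho_pta),
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      iti_range = iti_range,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Default per-cell target FAA derived from the published group summary
#'
#' The published summary reports FAA per group and emotion only; the default
#' targets use the same value in the relevant and irrelevant cells.
#'
#' @return Tibble with columns `group`, `emotion`, `relevance`, `faa`.
#' @export
default_cell_faa <- function() {
  ref <- reference_group_summary()
  tidyr::expand_grid(
    dplyr::select(ref, "group", "emotion", "faa"),
    relevance = c("irrelevant", "relevant")
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf(
    "  groups: Control %d, NonSymp %d, Symp %d (total %d)\n",
    x$n[["Control"]], x$n[["NonSymp"]], x$n[["Symp"]], sum(x$n)
  ))
  cat(sprintf(
    "  task: %d blocks x %d trials, ITI %.2f-%.2f s\n",
    x$n_blocks, x$trials_per_block, x$iti_range[1], x$iti_range[2]
  ))
  cat(sprintf(
    "  signal: alpha %.1f Hz, base F3 power %.2f uV^2, noise %.2f uV RMS\n",
    x$alpha_freq, x$base_power_f3, x$noise_rms
  ))
  cat(sprintf(
    "  blinks: %.1f/min, %.0f uV at VEOG, propagation %.2f\n",
    x$blink_rate, x$blink_amplitude, x$blink_propagation
  ))
  cat(sprintf(
    "  couplings (Spearman): BDI %.2f, RPQ %.2f, PTA %.2f; seed %d\n",
    x$rho[["bdi"]], x$rho[["rpq"]], x$rho[["pta"]], x$seed
  ))
  invisible(x)
}

#' Draw the latent subject layer of a synthetic cohort
#'
#' Realises per-subject per-cell FAA targets and the latent eFAA without
#' synthesising any EEG. Each subject receives a global FAA offset
#' (SD `sd_faa`) shared by all four emotion x relevance cells and an
#' emotional-modulation offset (SD `sd_efaa`) applied antisymmetrically to
#' the threat and neutral cells, so that the subject's latent eFAA is the
#' group eFAA plus the modulation offset. This layer is what the EEG
#' synthesis embeds as oscillation amplitudes, and is also usable directly
#' for statistical calibration studies at scale.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#' @return A tibble with one row per subject x emotion x relevance cell:
#'   `subject_id`, `group`, `emotion`, `relevance`, `faa_target` (the
#'   realised cell FAA), `faa_offset`, `efaa_latent`.
#' @export
simulate_subject_scores <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(as.integer(seed %||% spec$seed))

  groups <- rep(names(spec$n), times = spec$n)
  n_tot <- length(groups)
  ids <- sprintf("S%03d", seq_len(n_tot))
  faa_off <- rnorm(n_tot, 0, spec$sd_faa)
  efaa_off <- rnorm(n_tot, 0, spec$sd_efaa)

  subj <- tibble(
    subject_id = ids, group = groups,
    faa_offset = faa_off, efaa_offset = efaa_off
  )
  cells <- dplyr::inner_join(subj, spec$cell_faa,
    by = "group", relationship = "many-to-many"
  )
  cells <- dplyr::mutate(cells,
    faa_target = .data$faa + .data$faa_offset +
      ifelse(.data$emotion == "threat", 0.5, -0.5) * .data$efaa_offset
  )
  group_efaa <- dplyr::summarise(
    dplyr::group_by(spec$cell_faa, .data$group),
    g_efaa = mean(.data$faa[.data$emotion == "threat"]) -
      mean(.data$faa[.data$emotion == "neutral"]),
    .groups = "drop"
  )
  cells <- dplyr::inner_join(cells, group_efaa, by = "group")
  cells$efaa_latent <- cells$g_efaa + cells$efaa_offset
  dplyr::select(
    cells, "subject_id", "group", "emotion", "relevance",
    "faa_target", "faa_offset", "efaa_latent"
  )
}

#' Simulate a subject-level scores table without EEG synthesis
#'
#' Produces the same table [subject_scores()] yields after the full EEG
#' chain, but directly from the latent layer: per-cell FAA is the realised
#' target plus independent Gaussian measurement noise, and questionnaire
#' scores are copula-coupled to the latent eFAA. This is the fast path for
#' statistical calibration studies (type-I error, power) where synthesising
#' and re-analysing signals per seed would add nothing: the EEG stage's
#' fidelity is checked separately by the deterministic signal-chain tests.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#' @param measurement_sd SD of per-cell FAA measurement noise (ln-ratio;
#'   default 0.012, the per-cell error the full-scale EEG chain itself
#'   produces under the default signal model: measured as the SD of
#'   recovered-minus-target cell FAA over full 16-block syntheses at the
#'   default noise and blink settings).
#' @return A `faa_scores` tibble (as from [subject_scores()]) with group
#'   labels and questionnaire covariates joined.
#' @export
simulate_scores_table <- function(spec, seed = NULL, measurement_sd = 0.012) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed %||% spec$seed)
  latent <- simulate_subject_scores(spec, seed = seed)
  local_seed(seed + 1L)
  latent$faa_meas <- latent$faa_target +
    rnorm(nrow(latent), 0, measurement_sd)

  cells <- tidyr::pivot_wider(
    dplyr::select(latent, "subject_id", "emotion", "relevance", "faa_meas"),
    names_from = c("emotion", "relevance"), values_from = "faa_meas",
    names_prefix = "faa_"
  )
  out <- dplyr::mutate(cells,
    faa_threat = (.data$faa_threat_relevant + .data$faa_threat_irrelevant) / 2,
    faa_neutral = (.data$faa_neutral_relevant + .data$faa_neutral_irrelevant) / 2,
    faa_overall = (.data$faa_threat + .data$faa_neutral) / 2,
    efaa_relevant = .data$faa_threat_relevant - .data$faa_neutral_relevant,
    efaa_irrelevant = .data$faa_threat_irrelevant - .data$faa_neutral_irrelevant,
    efaa = (.data$efaa_relevant + .data$efaa_irrelevant) / 2
  )
  subjects <- dplyr::distinct(latent, .data$subject_id, .data$group,
                              .data$efaa_latent)
  q <- generate_questionnaires(
    setNames(subjects$efaa_latent, subjects$subject_id),
    subjects$group, spec, seed = seed + 2L
  )
  out <- dplyr::left_join(out, q, by = "subject_id")
  class(out) <- c("faa_scores", class(out))
  out
}
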