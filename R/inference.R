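#' Run the full inference battery on subject-level FAA/eFAA scores
#'
#' Executes, in order:
#' 1. Two-group (Control vs. mild-TBI) mixed ANOVA on cell FAA with
#'    Emotion and Relevance as within factors, after the pooled
#'    mean +/- 2.5 SD outlier rule on overall FAA.
#' 2. The same ANOVA with subjects at or above the 10-point BDI
#'    mild-depression cut-off excluded.
#' 3. The three-group FAA ANOVA (Control, non-symptomatic, symptomatic);
#'    when the Group x Emotion interaction is significant at 0.05 the data
#'    are split by emotion and per-condition group ANOVAs are run.
#' 4. The eFAA ANOVA (three-level Group x Relevance) after the outlier
#'    rule on scalar eFAA, followed by Holm-corrected pairwise Welch t
#'    tests on scalar eFAA.
#' 5. Levene (Brown-Forsythe) homogeneity checks and rank-based
#'    confirmations (Wilcoxon for two groups, Kruskal-Wallis for three)
#'    on the original, outlier-included data.
#' 6. The Spearman battery: eFAA against BDI, RPQ, RPQ-Emotional, BRIEF
#'    GEC, BRIEF Emotional Control and age over all groups, and against
#'    PTA and months post-injury over the mild-TBI subjects only; the
#'    outlier rule is applied pairwise to both variables before each
#'    correlation.
#'
#' Every exclusion (outliers, depression screen) is recorded with subject
#' ids in the `exclusions` element.
#'
#' @param scores A [subject_scores()] tibble with group labels and
#'   questionnaire covariates joined.
#' @param outlier_k Outlier-rule multiplier (default 2.5).
#' @param bdi_cutoff Depression-screen exclusion threshold (default 10,
#'   "10 or more points").
#' @param alpha Significance threshold used only to decide follow-up
#'   splits (default 0.05).
#' @return Object of class `faa_inference`: a named list of result tables
#'   (`anova_two_group`, `anova_two_group_no_depression`,
#'   `anova_three_group`, `emotion_split`, `anova_efaa`, `posthoc_efaa`,
#'   `levene`, `rank_confirmations`, `correlations`, `exclusions`).
#' @export
run_full_inference <- function(scores, outlier_k = 2.5, bdi_cutoff = 10,
                               alpha = 0.05) {
  need <- c("subject_id", "group", "efaa", "faa_overall")
  if (!all(need %in% names(scores))) {
    abort("`scores` must come from subject_scores() with groups joined.")
  }
  exclusions <- list()

  cell_cols <- grep("^faa_(threat|neutral)_(relevant|irrelevant)$",
                    names(scores), value = TRUE)
  long <- tidyr::pivot_longer(
    dplyr::select(scores, "subject_id", "group", dplyr::all_of(cell_cols)),
    cols = dplyr::all_of(cell_cols),
    names_to = c("emotion", "relevance"), names_pattern = "faa_(.*)_(.*)",
    values_to = "faa"
  )
  long$group2 <- ifelse(long$group == "Control", "Control", "MTBI")
  scores$group2 <- ifelse(scores$group == "Control", "Control", "MTBI")

  # (1) two-group FAA ANOVA after pooled outlier removal on overall FAA
  faa_out <- remove_outliers(scores, "faa_overall", outlier_k)
  exclusions$faa_outliers <- faa_out$removed$subject_id
  keep1 <- long[long$subject_id %in% faa_out$kept$subject_id, ]
  anova2 <- mixed_anova(keep1, "faa", "group2", c("emotion", "relevance"))

  # (2) depression-screened re-analysis
  depressed <- scores$subject_id[!is.na(scores$bdi) & scores$bdi >= bdi_cutoff]
  exclusions$depression_screen <- depressed
  keep2 <- keep1[!keep1$subject_id %in% depressed, ]
  anova2_nd <- mixed_anova(keep2, "faa", "group2", c("emotion", "relevance"))

  # (3) three-group FAA ANOVA with emotion-split follow-ups
  anova3 <- mixed_anova(keep1, "faa", "group", c("emotion", "relevance"))
  eff3 <- tidy(anova3)
  ixn_p <- eff3$p_value[eff3$effect == "group:emotion"]
  emotion_split <- NULL
  if (length(ixn_p) == 1 && is.finite(ixn_p) && ixn_p < alpha) {
    emotion_split <- purrr::map_dfr(unique(keep1$emotion), function(em) {
      sub <- keep1[keep1$emotion == em, ]
      a <- mixed_anova(sub, "faa", "group", "relevance")
      dplyr::bind_cols(tibble(emotion = em), tidy(a))
    })
  }

  # (4) eFAA ANOVA (3-level group x relevance) + Holm-Welch post-hocs
  efaa_out <- remove_outliers(scores, "efaa", outlier_k)
  exclusions$efaa_outliers <- efaa_out$removed$subject_id
  efaa_long <- tidyr::pivot_longer(
    dplyr::select(efaa_out$kept, "subject_id", "group",
                  "efaa_relevant", "efaa_irrelevant"),
    cols = c("efaa_relevant", "efaa_irrelevant"),
    names_to = "relevance", names_prefix = "efaa_", values_to = "efaa_cell"
  )
  anova_efaa <- mixed_anova(efaa_long, "efaa_cell", "group", "relevance")

  pairs <- utils::combn(sort(unique(efaa_out$kept$group)), 2, simplify = FALSE)
  posthoc <- purrr::map_dfr(pairs, function(pr) {
    a <- efaa_out$kept$efaa[efaa_out$kept$group == pr[1]]
    b <- efaa_out$kept$efaa[efaa_out$kept$group == pr[2]]
    dplyr::bind_cols(tibble(group_a = pr[1], group_b = pr[2]), welch_t(a, b))
  })
  posthoc$p_holm <- holm_adjust(posthoc$p_value)

  # (5) homogeneity and rank-based confirmations on the original data
  levene <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(comparison = "faa_two_group"),
                     levene_median(scores$faa_overall, scores$group2)),
    dplyr::bind_cols(tibble(comparison = "faa_three_group"),
                     levene_median(scores$faa_overall, scores$group)),
    dplyr::bind_cols(tibble(comparison = "efaa_three_group"),
                     levene_median(scores$efaa, scores$group))
  )
  rank_conf <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(comparison = "faa_two_group"),
                     rank_tests(scores$faa_overall, scores$group2)),
    dplyr::bind_cols(tibble(comparison = "faa_three_group"),
                     rank_tests(scores$faa_overall, scores$group)),
    dplyr::bind_cols(tibble(comparison = "efaa_three_group"),
                     rank_tests(scores$efaa, scores$group))
  )

  # (6) Spearman battery with the pairwise outlier rule
  all_vars <- c("bdi", "rpq", "rpq_emotional", "brief_gec", "brief_ec", "age")
  mtbi_vars <- c("pta_hours", "months_post_injury")
  correlations <- purrr::map_dfr(
    c(all_vars, mtbi_vars),
    function(v) {
      if (!v %in% names(scores)) return(NULL)
      sub <- if (v %in% mtbi_vars) scores[scores$group2 == "MTBI", ] else scores
      res <- pairwise_outlier_spearman(sub$efaa, sub[[v]],
                                       sub$subject_id, outlier_k)
      dplyr::bind_cols(tibble(variable = v), res)
    }
  )
  exclusions$correlation_outliers <- setNames(
    correlations$removed_ids, correlations$variable
  )
  correlations$removed_ids <- NULL

  structure(
    list(
      anova_two_group = anova2,
      anova_two_group_no_depression = anova2_nd,
      anova_three_group = anova3,
      emotion_split = emotion_split,
      anova_efaa = anova_efaa,
      posthoc_efaa = posthoc,
      levene = levene,
      rank_confirmations = rank_conf,
      correlations = correlations,
      exclusions = exclusions,
      params = list(outlier_k = outlier_k, bdi_cutoff = bdi_cutoff,
                    alpha = alpha)
    ),
    class = "faa_inference"
  )
}

# Spearman correlation after applying the mean +/- k SD rule to both
# variables of the pair (pooled, single pass, strict exceedance).
pairwise_outlier_spearman <- function(x, y, ids, k = 2.5) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; ids <- ids[ok]
  keep <- rep(TRUE, length(x))
  for (v in list(x, y)) {
    if (sd(v) > 0) {
      r <- outlier_bounds(v, k)
      keep <- keep & v >= r$lower & v <= r$upper
    }
  }
  res <- spearman_cor(x[keep], y[keep])
  dplyr::bind_cols(
    res,
    tibble(n_removed = sum(!keep),
           removed_ids = list(ids[!keep]))
  )
}

#' @export
print.faa_inference <- function(x, ...) {
  cat("<faa_inference>\n\n-- FAA two-group ANOVA --\n")
  print(x$anova_two_group)
  cat("\n-- eFAA ANOVA (three groups x relevance) --\n")
  print(x$anova_efaa)
  cat("\n-- eFAA pairwise Welch post-hocs (Holm) --\n")
  print(as.data.frame(x$posthoc_efaa), digits = 3, row.names = FALSE)
  cat("\n-- Spearman battery --\n")
  print(as.data.frame(x$correlations), digits = 3, row.names = FALSE)
  n_excl <- sum(lengths(x$exclusions[c("faa_outliers", "efaa_outliers")]))
  cat(sprintf("\n%d subject-level outlier exclusion(s); see $exclusions.\n",
              n_excl))
  invisible(x)
}

#' Flatten an inference battery into one tidy table
#'
#' @param x A `faa_inference` object.
#' @param ... Unused.
#' @return Tibble with columns `analysis`, `term`, `statistic`, `df_num`,
#'   `df_den`, `p_value`, `effect_size`.
#' @method tidy faa_inference
#' @export
tidy.faa_inference <- function(x, ...) {
  an <- function(obj, label) {
    t <- tidy(obj)
    tibble(analysis = label, term = t$effect, statistic = t$statistic,
           df_num = t$df_num, df_den = t$df_den, p_value = t$p_value,
           effect_size = t$ges)
  }
  dplyr::bind_rows(
    an(x$anova_two_group, "faa_two_group"),
    an(x$anova_two_group_no_depression, "faa_two_group_no_depression"),
    an(x$anova_three_group, "faa_three_group"),
    an(x$anova_efaa, "efaa"),
    tibble(
      analysis = "efaa_posthoc",
      term = paste(x$posthoc_efaa$group_a, "vs", x$posthoc_efaa$group_b),
      statistic = x$posthoc_efaa$statistic,
      df_num = NA_real_, df_den = x$posthoc_efaa$df,
      p_value = x$posthoc_efaa$p_holm, effect_size = NA_real_
    ),
    tibble(
      analysis = "spearman",
      term = paste("efaa vs", x$correlations$variable),
      statistic = x$correlations$rho,
      df_num = NA_real_, df_den = x$correlations$n - 2,
      p_value = x$correlations$p_value, effect_size = x$correlations$rho
    )
  )
}

#' Write an inference battery as machine-readable JSON
#'
#' @param x A `faa_inference` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_inference_json <- function(x, path) {
  stopifnot(inherits(x, "faa_inference"))
  payload <- list(
    tests = tidy(x),
    levene = x$levene,
    rank_confirmations = x$rank_confirmations,
    exclusions = x$exclusions,
    params = x$params
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
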