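# Shared fixtures: small task plans and cohort specs sized for unit tests.

tiny_spec <- function(..., noise_rms = 0, blink_rate = 0, seed = 7L) {
  cohort_spec(
    n_control = 2, n_nonsymp = 2, n_symp = 2,
    n_blocks = 4L, trials_per_block = 8L,
    noise_rms = noise_rms, blink_rate = blink_rate,
    seed = seed, ...
  )
}

tiny_events <- function(seed = 3L, n_blocks = 4L, trials_per_block = 8L) {
  generate_task_events(seed, n_blocks = n_blocks,
                       trials_per_block = trials_per_block)
}

# one subject's condition cells at a flat FAA target
flat_cells <- function(faa = 0) {
  cells <- tidyr::expand_grid(
    emotion = c("neutral", "threat"),
    relevance = c("irrelevant", "relevant")
  )
  cells$faa_target <- faa
  cells$subject_id <- "s1"
  cells
}

# run the preprocessing + spectral + asymmetry chain for one subject
chain_scores <- function(rec, min_segments = 1, ocular = "regression") {
  segs <- suppressMessages(preprocess_recording(rec, ocular = ocular))
  at <- suppressMessages(
    condition_alpha_table(segs, min_segments = min_segments)
  )
  suppressMessages(subject_scores(at))
}

# Independent mixed-design ANOVA oracle: sequential linear-model projections
# (lm + anova) on the full fixed-effects decomposition with subject terms
# entered after the group terms they contain. In a balanced design the
# sums of squares are orthogonal, so this reproduces the classical
# repeated-measures partition without using aov's Error() machinery.
# Returns a data.frame: effect, ss, df_num, df_den, statistic (F).
oracle_mixed_anova <- function(data, dv, between, within = character(),
                               subject = "subject_id") {
  d <- data.frame(
    y = data[[dv]],
    g = factor(data[[between]]),
    s = factor(data[[subject]])
  )
  wn <- vapply(seq_along(within), function(i) paste0("w", i), "")
  for (i in seq_along(within)) d[[wn[i]]] <- factor(data[[within[i]]])

  terms <- c("g", "s")
  for (w in wn) terms <- c(terms, w, paste0("g:", w))
  if (length(wn) == 2) {
    terms <- c(terms, "w1:w2", "g:w1:w2", "s:w1", "s:w2")
  }
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  # saturated when there is no within factor (0-df residual): harmless here
  an <- suppressWarnings(stats::anova(stats::lm(fml, data = d)))
  ss <- an[, "Sum Sq"]
  df <- an[, "Df"]
  names(ss) <- names(df) <- rownames(an)

  fval <- function(num, den) {
    (ss[[num]] / df[[num]]) / (ss[[den]] / df[[den]])
  }
  rows <- list()
  add <- function(label, num, den) {
    rows[[length(rows) + 1]] <<- data.frame(
      effect = label, ss = ss[[num]], df_num = df[[num]],
      df_den = df[[den]], statistic = fval(num, den)
    )
  }
  add(between, "g", "s")
  if (length(wn) == 1) {
    add(within[1], "w1", "Residuals")
    add(paste0(between, ":", within[1]), "g:w1", "Residuals")
  } else if (length(wn) == 2) {
    add(within[1], "w1", "s:w1")
    add(paste0(between, ":", within[1]), "g:w1", "s:w1")
    add(within[2], "w2", "s:w2")
    add(paste0(between, ":", within[2]), "g:w2", "s:w2")
    add(paste(within, collapse = ":"), "w1:w2", "Residuals")
    add(paste(c(between, within), collapse = ":"), "g:w1:w2", "Residuals")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random balanced mixed design for oracle-equivalence checks
random_design <- function(seed) {
  set.seed(seed)
  n_groups <- sample(2:3, 1)
  n_within <- sample(0:2, 1)
  n_per_g <- sample(3:6, n_groups, replace = TRUE)
  within <- c("w1", "w2")[seq_len(n_within)]
  subj <- sprintf("s%02d", seq_len(sum(n_per_g)))
  d <- data.frame(subject_id = subj,
                  group = rep(letters[seq_len(n_groups)], n_per_g))
  for (w in within) {
    d <- merge(d, setNames(data.frame(x = c("lo", "hi")), w))
  }
  d$y <- rnorm(nrow(d)) +
    0.8 * (d$group == "a") +
    if (n_within >= 1) 0.4 * (d$w1 == "hi") * (d$group == "b") else 0
  list(data = d, within = within)
}
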