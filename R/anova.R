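#' Mixed-design repeated-measures ANOVA with generalized eta squared
#'
#' Univariate sums-of-squares partition for a design with one
#' between-subjects factor and up to two two-level within-subject factors:
#' subjects-within-group is the error stratum for the between effect, and
#' each within effect or interaction is tested against its factor x
#' subjects-within-group stratum (the classical repeated-measures
#' partition, computed via `stats::aov` with `Error()` strata). Two-level
#' within factors need no sphericity correction. Generalized eta squared
#' is computed with all error strata in the denominator:
#' `ges = SS_effect / (SS_effect + sum of all residual SS)`.
#'
#' Every subject must have a value in every within-factor cell and each
#' group needs at least two subjects. If all responses are identical the
#' partition is degenerate; effects are reported with `F = 0` and a
#' `degenerate` flag.
#'
#' @param data Tidy tibble, one row per subject x within-cell.
#' @param dv Name of the response column.
#' @param between Name of the grouping column.
#' @param within Character vector (0–2 names) of within-factor columns.
#' @param subject Name of the subject id column (default "subject_id").
#' @return Object of class `faa_anova`: a list with `effects` (tibble:
#'   `effect`, `df_num`, `df_den`, `statistic`, `p_value`, `ges`),
#'   `design`, and `n_subjects`. [tidy()] returns the effect table,
#'   [glance()] the design descriptor.
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:8),
#'                         emotion = c("neutral", "threat"))
#' d$group <- rep(c("a", "b"), each = 8)
#' d$faa <- stats::rnorm(nrow(d)) + ifelse(d$group == "a", 0.5, 0)
#' tidy(mixed_anova(d, "faa", "group", "emotion"))
mixed_anova <- function(data, dv, between, within = character(),
                        subject = "subject_id") {
  cols <- c(dv, between, within, subject)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (length(within) > 2) abort("At most two within factors are supported.")

  d <- data.frame(
    y = data[[dv]],
    g = factor(data[[between]]),
    s = factor(data[[subject]])
  )
  for (i in seq_along(within)) d[[paste0("w", i)]] <- factor(data[[within[i]]])

  # completeness: every subject in every within cell exactly once
  n_cells <- prod(vapply(seq_along(within),
                         function(i) nlevels(d[[paste0("w", i)]]), 1))
  tab <- table(d$s)
  if (any(tab != n_cells)) {
    abort("Every subject must have exactly one value per within cell.")
  }
  if (nlevels(d$g) < 2) abort("Need at least 2 groups with data.")
  per_group <- rowSums(table(d$g, d$s) > 0)
  if (any(per_group < 2)) abort("Each group needs at least 2 subjects.")

  # NB: paste0("w", integer(0)) is "w", not character(0)
  wnames <- vapply(seq_along(within), function(i) paste0("w", i), "")
  rhs <- paste(c("g", wnames), collapse = " * ")
  err <- if (length(wnames) > 0) {
    sprintf("Error(s/(%s))", paste(wnames, collapse = " * "))
  } else {
    "Error(s)"
  }
  fml <- stats::as.formula(paste("y ~", rhs, "+", err))
  fit <- aov(fml, data = d)
  sm <- summary(fit)

  rows <- list()
  resid_ss <- 0
  for (stratum in sm) {
    a <- stratum[[1]]
    rn <- trimws(rownames(a))
    is_res <- rn == "Residuals"
    resid_ss <- resid_ss + sum(a[is_res, "Sum Sq"])
    df_den <- a[is_res, "Df"]
    for (j in which(!is_res)) {
      rows[[length(rows) + 1]] <- tibble(
        effect = rn[j],
        df_num = a[j, "Df"],
        df_den = df_den,
        ss = a[j, "Sum Sq"],
        ms_err = a[is_res, "Mean Sq"]
      )
    }
  }
  eff <- dplyr::bind_rows(rows)

  # strata with only round-off variance are reported as degenerate (F = 0
  # for a null effect, Inf for a real one), not as ratios of round-off
  # round-off SS from exactly-equal responses is O(n * (eps * |y|)^2)
  tiny <- 1e-20 * mean(d$y^2) * nrow(d) + 1e-300
  all_zero <- (resid_ss + sum(eff$ss)) < tiny
  eff <- dplyr::mutate(eff,
    statistic = dplyr::if_else(
      .data$ms_err > tiny,
      (.data$ss / .data$df_num) / .data$ms_err,
      dplyr::if_else(.data$ss / .data$df_num > tiny, Inf, 0)
    ),
    p_value = dplyr::if_else(
      is.finite(.data$statistic) & .data$ms_err > tiny,
      stats::pf(.data$statistic, .data$df_num, .data$df_den,
                lower.tail = FALSE),
      dplyr::if_else(.data$statistic > 0, 0, 1)
    ),
    ges = dplyr::if_else(
      .data$ss + resid_ss > 0, .data$ss / (.data$ss + resid_ss), 0
    )
  )
  # report the factors under their user-facing names
  rename_map <- c(g = between, setNames(within, wnames))
  eff$effect <- vapply(strsplit(eff$effect, ":", fixed = TRUE), function(p) {
    paste(rename_map[p], collapse = ":")
  }, "")

  structure(
    list(
      effects = dplyr::select(eff, "effect", "df_num", "df_den",
                              "statistic", "p_value", "ges", "ss"),
      design = list(between = between,
                    between_levels = levels(d$g),
                    within = within, dv = dv),
      n_subjects = nlevels(d$s),
      degenerate = all_zero
    ),
    class = "faa_anova"
  )
}

#' @export
print.faa_anova <- function(x, ...) {
  cat(sprintf(
    "<faa_anova> %s ~ %s%s, %d subjects%s\n",
    x$design$dv, x$design$between,
    if (length(x$design$within) > 0) {
      paste0(" x ", paste(x$design$within, collapse = " x "))
    } else "",
    x$n_subjects,
    if (x$degenerate) " [degenerate variance]" else ""
  ))
  print(as.data.frame(x$effects[, c("effect", "df_num", "df_den",
                                    "statistic", "p_value", "ges")]),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname mixed_anova
#' @param x A `faa_anova` object.
#' @param ... Unused.
#' @method tidy faa_anova
#' @export
tidy.faa_anova <- function(x, ...) {
  dplyr::select(x$effects, "effect", "df_num", "df_den", "statistic",
                "p_value", "ges")
}

#' @rdname mixed_anova
#' @method glance faa_anova
#' @export
glance.faa_anova <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    between = x$design$between,
    n_groups = length(x$design$between_levels),
    within = paste(x$design$within, collapse = ","),
    degenerate = x$degenerate
  )
}
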