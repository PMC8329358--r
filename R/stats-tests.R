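#' Welch's unequal-variance t test
#'
#' Two-sided Welch t with Satterthwaite degrees of freedom (the fractional
#' df variant), via [stats::t.test()].
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @return Tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(tibble(statistic = 0, df = length(values_a) + length(values_b) - 2,
                    p_value = 1, mean_a = mean(values_a), mean_b = mean(values_b)))
    }
    abort("Degenerate variance in both groups.")
  }
  tt <- t.test(values_a, values_b, var.equal = FALSE)
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(values_a), mean_b = mean(values_b)
  )
}

#' Holm step-down multiple-comparison adjustment
#'
#' Step-down Holm: sort ascending, multiply the i-th smallest by
#' `m - i + 1`, enforce monotonicity by running maximum, cap at 1, return
#' in the original order (via [stats::p.adjust()]).
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(p, method = "holm")
}

#' Levene/Brown-Forsythe homogeneity-of-variance test
#'
#' Brown-Forsythe variant: a one-way ANOVA on absolute deviations from the
#' group medians (the default of the car package, which is used as the
#' engine).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return Tibble: `statistic` (W), `df_num`, `df_den`, `p_value`.
#' @export
levene_median <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("Need at least 2 groups.")
  if (any(table(groups) < 2)) abort("Each group needs at least 2 values.")
  # near-perfect deviation fits in tiny groups trigger a harmless warning
  lt <- suppressWarnings(car::leveneTest(values, groups, center = median))
  tibble(
    statistic = lt[1, "F value"],
    df_num = lt[1, "Df"], df_den = lt[2, "Df"],
    p_value = lt[1, "Pr(>F)"]
  )
}

#' Rank-based group comparison
#'
#' Wilcoxon rank-sum for two groups, Kruskal-Wallis for three or more,
#' with midrank ties and tie-corrected variance. The Wilcoxon p value is
#' exact (enumeration) for small samples without ties and a normal
#' approximation otherwise, the `stats` defaults.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return Tibble: `test` ("wilcoxon" or "kruskal"), `statistic`,
#'   `p_value`.
#' @export
rank_tests <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2) {
    abort("Need at least 2 non-empty groups.")
  }
  if (nlevels(groups) == 2) {
    # tie warnings are expected with integer questionnaire scores
    wt <- suppressWarnings(wilcox.test(values ~ groups))
    tibble(test = "wilcoxon", statistic = unname(wt$statistic),
           p_value = wt$p.value)
  } else {
    kt <- kruskal.test(values, groups)
    tibble(test = "kruskal", statistic = unname(kt$statistic),
           p_value = kt$p.value)
  }
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; the p value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' two-sided. Ties are handled by midranks.
#'
#' @param x,y Paired numeric vectors, n >= 3; pairs with missing values
#'   are dropped.
#' @return Tibble of class `faa_cor`: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) abort("Zero rank variance.")
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  out <- tibble(rho = rho, p_value = p, n = n)
  class(out) <- c("faa_cor", class(out))
  out
}
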