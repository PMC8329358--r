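#' Generate questionnaire and clinical scores coupled to latent eFAA
#'
#' Scores are generated by a Gaussian copula: the latent eFAA values are
#' rank-transformed to normal scores, a correlated normal deviate is drawn
#' at the Pearson correlation `r = 2 sin(pi * rho / 6)` that yields the
#' requested Spearman `rho` for a bivariate Gaussian copula, and the
#' correlated deviate is pushed through a skewed count marginal. Marginals:
#'
#' * BDI: rounded Gamma(shape 1.2), scaled so ~15% of subjects reach the
#'   mild-depression cut-off of 10 points.
#' * RPQ: symptomatic mild-TBI subjects score `1 +` a rounded Gamma
#'   (the group is defined by reporting at least one symptom);
#'   non-symptomatic subjects are forced to 0; controls draw from a
#'   zero-inflated rounded Gamma.
#' * RPQ-Emotional: a Binomial(RPQ, 0.3) subset of the RPQ total.
#' * PTA (mild-TBI only): Gamma-distributed hours, truncated below 24 h
#'   (the mild-TBI criterion), coupled at `rho_pta` within the mild-TBI
#'   subset.
#' * BRIEF GEC and Emotional Control: T-score-like Normal(50, 10), rounded;
#'   uncoupled.
#' * Age: Normal(41, 11), clamped to 18–65; months post-injury
#'   (mild-TBI only): uniform 9–37.
#'
#' Monotone marginal transforms preserve Spearman correlation up to the
#' attenuation introduced by integer ties and structural zeros; for the BDI
#' coupling the empirical Spearman over a large cohort lands within ±0.05
#' of the target.
#'
#' @param latent_efaa Numeric vector of latent eFAA values, one per subject.
#' @param groups Character vector of group labels ("Control", "NonSymp",
#'   "Symp"), same length.
#' @param spec A [cohort_spec()] supplying the coupling targets.
#' @param seed Integer seed.
#' @return Tibble with columns `subject_id` (if supplied via names of
#'   `latent_efaa`), `group`, `rpq`, `rpq_emotional`, `bdi`, `brief_gec`,
#'   `brief_ec`, `age`, `pta_hours`, `months_post_injury` (the last two are
#'   `NA` for controls).
#' @export
generate_questionnaires <- function(latent_efaa, groups, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(latent_efaa) != length(groups)) {
    abort("`latent_efaa` and `groups` must have equal length.")
  }
  if (any(abs(spec$rho) >= 1)) abort("Coupling rhos must have magnitude < 1.")
  local_seed(as.integer(seed))
  n <- length(latent_efaa)
  is_mtbi <- groups %in% c("NonSymp", "Symp")

  z_efaa <- qnorm(rank(latent_efaa, ties.method = "average") / (n + 1))
  z_efaa <- z_efaa / sd(z_efaa)

  couple <- function(z, rho) {
    r <- 2 * sin(pi * rho / 6)           # Spearman -> Pearson for the copula
    pnorm(r * z + sqrt(1 - r^2) * rnorm(length(z)))
  }

  # BDI: ~15% at or above the 10-point mild-depression cut-off
  bdi_scale <- 9.5 / qgamma(0.85, shape = 1.2)
  u_bdi <- couple(z_efaa, spec$rho[["bdi"]])
  bdi <- as.integer(round(qgamma(u_bdi, shape = 1.2, scale = bdi_scale)))

  u_rpq <- couple(z_efaa, spec$rho[["rpq"]])
  rpq <- integer(n)
  rpq[groups == "Symp"] <- 1L +
    as.integer(round(qgamma(u_rpq[groups == "Symp"], shape = 1.5, scale = 5)))
  # controls: zero-inflated mild symptom counts
  ctrl <- groups == "Control"
  rpq[ctrl] <- as.integer(floor(qgamma(u_rpq[ctrl], shape = 0.6, scale = 3)))
  rpq[groups == "NonSymp"] <- 0L
  rpq_emotional <- rbinom(n, size = rpq, prob = 0.3)

  pta <- rep(NA_real_, n)
  if (any(is_mtbi)) {
    z_sub <- qnorm(rank(latent_efaa[is_mtbi], ties.method = "average") /
      (sum(is_mtbi) + 1))
    z_sub <- z_sub / sd(z_sub)
    u_pta <- couple(z_sub, spec$rho[["pta"]])
    pta[is_mtbi] <- pmin(qgamma(u_pta, shape = 1.2, scale = 3), 23.5)
  }

  tibble(
    subject_id = names(latent_efaa) %||% sprintf("S%03d", seq_len(n)),
    group = groups,
    rpq = rpq,
    rpq_emotional = as.integer(rpq_emotional),
    bdi = bdi,
    brief_gec = as.integer(round(rnorm(n, 50, 10))),
    brief_ec = as.integer(round(rnorm(n, 50, 10))),
    age = pmin(pmax(round(rnorm(n, 41, 11)), 18), 65),
    pta_hours = round(pta, 2),
    months_post_injury = ifelse(is_mtbi, round(runif(n, 9, 37), 1), NA_real_)
  )
}
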