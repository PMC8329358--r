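#' Published group-level summary values for FAA and eFAA
#'
#' Group-level means and standard deviations of alpha power, log alpha power,
#' FAA and eFAA at F3/F4 for the three study groups (healthy controls,
#' non-symptomatic mild-TBI, symptomatic mild-TBI), in the neutral and
#' threat emotion conditions, as reported for the clinical cohort this
#' package's methodology was developed on. These values serve two purposes:
#' they parameterise the default synthetic cohort (group sizes and effect
#' sizes), and [reproduce_table1()] checks their internal arithmetic
#' consistency (ln-difference gives the FAA column; the threat-minus-neutral
#' FAA difference gives the eFAA column).
#'
#' Power values are in the acquisition software's alpha-band area-under-curve
#' units and are treated as arbitrary-unit power; FAA and eFAA are
#' dimensionless ln-ratios.
#'
#' @return A tibble with one row per group x emotion condition and columns
#'   `group`, `emotion`, `f4`, `f4_sd`, `f3`, `f3_sd`, `ln_f4`, `ln_f4_sd`,
#'   `ln_f3`, `ln_f3_sd`, `faa`, `faa_sd`, plus per-group `efaa`, `efaa_sd`
#'   (repeated on both condition rows of a group).
#' @seealso [reference_outlier_stats()], [reproduce_table1()]
#' @export
#' @examples
#' reference_group_summary()
reference_group_summary <- function() {
  tibble::tribble(
    ~group,     ~emotion,  ~f4,   ~f4_sd, ~f3,   ~f3_sd, ~ln_f4, ~ln_f4_sd, ~ln_f3, ~ln_f3_sd, ~faa,   ~faa_sd, ~efaa,  ~efaa_sd,
    "Control",  "neutral", 5.004, 9.588,  5.225, 10.630, 0.788,  1.120,     0.732,  1.195,     0.057,  0.251,   0.003,  0.032,
    "Control",  "threat",  5.000, 9.399,  5.232, 10.525, 0.798,  1.121,     0.738,  1.200,     0.060,  0.255,   0.003,  0.032,
    "NonSymp",  "neutral", 4.749, 4.200,  5.773, 4.886,  1.180,  0.906,     1.395,  0.872,     -0.215, 0.336,   0.021,  0.034,
    "NonSymp",  "threat",  4.813, 4.320,  5.760, 4.971,  1.189,  0.915,     1.383,  0.885,     -0.194, 0.355,   0.021,  0.034,
    "Symp",     "neutral", 2.435, 2.421,  3.026, 3.486,  0.549,  0.777,     0.684,  0.845,     -0.135, 0.291,   -0.019, 0.036,
    "Symp",     "threat",  2.467, 2.503,  3.088, 3.524,  0.545,  0.799,     0.699,  0.860,     -0.154, 0.299,   -0.019, 0.036
  )
}

#' Pooled overall-FAA mean and SD used by the published outlier rule
#'
#' The outlier rule is mean +/- 2.5 x SD on the pooled (all groups together)
#' distribution of overall FAA; for the reference cohort the pooled mean was
#' -0.14 and the SD 0.41, giving bounds (-1.165, 0.885).
#'
#' @return A named list with elements `center`, `spread`, `k`.
#' @seealso [outlier_rule()]
#' @export
reference_outlier_stats <- function() {
  list(center = -0.14, spread = 0.41, k = 2.5)
}

#' Reference group sizes of the study cohort
#'
#' @return Named integer vector: Control, NonSymp, Symp counts.
#' @export
reference_group_sizes <- function() {
  c(Control = 17L, NonSymp = 12L, Symp = 15L)
}
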