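Package: efaa
Title: Task-Induced Frontal Alpha Asymmetry and Its Emotional Modulation from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes task-induced frontal alpha asymmetry (FAA = ln(F4) - ln(F3))
    and its emotional-modulation index (eFAA = FAA under threat-related stimuli
    minus FAA under neutral stimuli) from epoched multi-channel EEG. Provides the
    full processing chain (band-pass filtering, downsampling, regression-based
    ocular correction, Cz re-referencing, two-second epoching with 200 ms baseline
    correction, +/- 80 microvolt artifact rejection, Hann-windowed periodogram
    alpha-band area under the curve), the subject-level asymmetry scores with a
    mean +/- 2.5 SD outlier rule, mixed-design repeated-measures ANOVA with
    generalized eta squared, Holm-corrected Welch post-hoc tests, rank-based
    confirmations, and a Spearman correlation battery against questionnaire
    scores. A synthetic cohort generator emulates the Go/NoGo executive reaction
    time task (16 blocks of 64 trials with emotion, relevance and response-rule
    structure), alpha oscillations with configurable asymmetry, pink noise,
    blink artifacts, and Gaussian-copula-coupled questionnaire scores, so the
    whole pipeline is testable end to end without clinical data. BrainVision
    (.vhdr/.vmrk/.eeg) reading and writing is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
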