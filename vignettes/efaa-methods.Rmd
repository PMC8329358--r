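---
title: "Methods: measuring frontal alpha asymmetry and its emotional modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring frontal alpha asymmetry and its emotional modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efaa)
```

## The measurement model

Alpha-band (8–12 Hz) EEG power is inversely related to cortical
activation. Frontal alpha asymmetry compares the two frontal electrodes on
a log scale,

$$\mathrm{FAA} = \ln P_{F4} - \ln P_{F3},$$

where \(P\) is alpha-band power during the task. The log scale makes FAA a
pure ratio measure: any gain common to both electrodes — amplifier scaling,
skull conductivity, reference choice shared by both channels — cancels
exactly. The package asserts this as a property (scaling every channel by a
constant leaves FAA unchanged to 1e-10).

The emotional modulation index subtracts FAA measured in emotionally
neutral trials from FAA measured in threat-related trials,

$$\mathrm{eFAA} = \mathrm{FAA}_{\text{threat}} - \mathrm{FAA}_{\text{neutral}},$$

removing each subject's baseline asymmetry. Since the two trial types are
interleaved within the same blocks and differ only in the emotional figure
shown, eFAA isolates the effect of emotional content. Both indices are
computed per emotion × relevance cell, then combined by unweighted cell
means (cell-means logic, matching the ANOVA that consumes them), with
go/nogo trials pooled — the inference design has no response-type factor.

## The processing chain and its numerical choices

The chain is fixed, in this order, and recorded in provenance metadata:
band-pass 0.01–70 Hz → downsample 500 → 250 Hz → ocular regression →
re-reference to Cz → band-pass 0.1–30 Hz → 2-s epochs at stimulus onset →
200-ms baseline correction → ±80 µV rejection.

**Filtering.** The band-pass is the zero-phase (forward–backward)
response of a 4th-order Butterworth. It is applied in the frequency domain
as the squared magnitude \(|H(f)|^2 = [1+(f_{lo}/f)^{2n}]^{-1}
[1+(f/f_{hi})^{2n}]^{-1}\) on the FFT grid, with edge-reflection padding.
This is mathematically the response a time-domain forward–backward cascade
realises, but it remains numerically exact for corners as low as 0.01 Hz
at 500 Hz sampling, where transfer-function coefficient filtering loses
the passband entirely (we measured >30% amplitude error even at order 1).
Tests pin the response against the designed transfer function at 10 Hz
(pass, within 1%) and 60 Hz (stop, gain 1/(1+2^8)).

**Downsampling** decimates by an integer factor after an anti-alias
low-pass at 0.8× the new Nyquist; marker indices rescale by floor
division. All internal indexing is 0-based half-open; the vendor format's
1-based marker positions are converted at the I/O boundary only.

**Ocular correction.** Interactive ICA-based correction is not
reproducible in a pipeline, so the package uses deterministic Gratton-style
EOG regression: blink windows are detected on the EOG by a 3×MAD
threshold (falling back to the SD when the MAD is zero, as happens when
blinks are sparse on an otherwise quiet channel), dilated by 150 ms, and
each EEG channel's regression coefficient on the EOG over those windows is
subtracted. On noiseless synthetic blinks the coefficient recovers the
configured propagation factor exactly and ≥98% of blink epochs survive the
amplitude rule afterwards. An ICA hook is a possible extension; it is not
implemented.

**Rejection** flags a whole segment when any sample of any EEG analysis
channel (all scalp channels; the EOG is excluded once correction has run)
is strictly beyond ±80 µV. Strictness follows the rule's wording: exactly
±80.0 is kept. Rejection counts are logged per condition and the
conservation identity (segments in = kept + rejected + skipped) is
asserted.

**Spectral estimation** uses a single-taper Hann periodogram per 2-s
epoch (0.5 Hz resolution, so the 8 and 12 Hz edges fall on grid points),
normalised so the integral of the density over [0, Nyquist] equals the
windowed signal's mean square with the window power compensated
(Parseval-consistent; a unit sinusoid integrates to 0.5 µV² within 1%).
Alpha power is the trapezoidal area under the curve over [8, 12] Hz,
endpoints inclusive. Per subject × electrode × condition the per-segment
AUCs are averaged over retained segments and the natural log is taken
*after* averaging — the order fixed by the definition of the group summary
(log of the condition-mean power). Cells with fewer than `min_segments`
(default 10) retained segments are marked missing and the subject is
excluded from inference, with a logged id. The AUC is floored at 1e-12 µV²
before the log to guard degenerate input.

## The outlier rule and the inference battery

Outliers are defined as mean ± 2.5 SD of the *pooled* (all groups
together) distribution of the score under analysis; the sample SD uses the
n−1 denominator, removal is single-pass, and only strict exceedance
removes. The rule is re-applied per analysis — overall FAA before the FAA
ANOVAs, scalar eFAA before the eFAA ANOVA, and pairwise (both variables)
before each correlation — mirroring per-analysis exclusion practice; every
removal is logged by subject id. A per-group variant of the rule is
deliberately not the default: the published bounds derive from a single
pooled mean and SD.

The mixed-design ANOVA partitions sums of squares classically: subjects
within group is the error stratum for the between effect; each within
effect and its group interaction is tested against its factor × subjects
stratum. With two-level within factors sphericity holds trivially and no
correction is applied. Generalized eta squared uses all error strata in
the denominator,
\(\eta^2_G = SS_{\text{effect}} / (SS_{\text{effect}} + \sum SS_{\text{error}})\),
the measured-variance convention; the observed/manipulated distinction is
not modelled. The engine is `stats::aov` with `Error()` strata; the test
suite verifies F, dfs and p against an independent sequential
linear-model projection oracle to 1e-8 on 100 random balanced designs, and
type-I error for the Group effect is calibrated to [0.03, 0.07] over 1000
null-cohort simulations. Strata whose variance is pure round-off (exactly
equal responses) are reported as degenerate with F = 0 rather than as
ratios of round-off noise.

Post-hoc group contrasts use Welch's unequal-variance t (fractional
Satterthwaite df) with Holm correction across the three pairs. Levene's
test is the Brown–Forsythe variant (deviations from group medians), and
rank-based confirmations (Wilcoxon rank-sum, Kruskal–Wallis) run on the
original data *with* outliers included, as a robustness check. All tests
are two-sided; 0.05 is a reporting threshold only, except that the
Group × Emotion interaction at 0.05 triggers the emotion-split follow-up
ANOVAs. The post-hoc family for the three-group FAA ANOVA is implemented
as Holm-corrected pairwise Welch tests; this is an interpretation, since a
pairwise family can be composed in several ways, and it matches the
fractional dfs reported for the eFAA contrasts.

Correlations are Spearman's rho (Pearson on midranks, t-approximation p),
chosen because questionnaire counts are strongly skewed; the BDI ≥ 10
re-analysis removes subjects at or above the mild-depression cut-off.

## What the synthetic cohort emulates

The generator reproduces the study conditions as defaults: group sizes
17/12/15 (Control / non-symptomatic mTBI / symptomatic mTBI); group-level
FAA and eFAA equal to the published group summary
(`reference_group_summary()`), with the same target in the relevant and
irrelevant cells since the summary does not split by relevance; and
questionnaire couplings eFAA↔BDI −0.52, eFAA↔RPQ −0.34, eFAA↔PTA +0.41.

The subject layer draws, per subject, a global FAA offset (SD 0.30, the
scale of the published per-group FAA SDs) shared by all four cells, plus
an emotional-modulation offset (SD 0.034, the scale of the published eFAA
SDs) applied antisymmetrically to threat and neutral cells — so the
between-subject FAA spread is large while eFAA spread stays small, exactly
the variance structure the published SDs describe.

The signal layer synthesises 500 Hz recordings over the minimal montage
{F3, F4, Fz, Cz, VEOG}: per trial, a 10 Hz oscillation spans the 2-s
analysis window with random phase and a Hann amplitude envelope (avoiding
epoch-edge discontinuities). A sinusoid of amplitude \(A\) carries power
\(A^2/2\); the generator calibrates \(A\) in closed form against the
analysis pipeline's own taper — the envelope–taper overlap factor
\(\sum w^2 / \sum w^2 h^2\) — so the requested alpha AUC is recovered
exactly on clean signals (verified by a periodogram oracle to 1%, and FAA
to machine precision since calibration errors are common-mode across
electrodes). Pink (1/f) noise at 2 µV RMS rides on every EEG channel.
Blinks are Poisson events (12/min) with a 0.3-s raised-cosine waveform,
500 µV at VEOG and a 0.3 propagation factor onto frontal channels. The
blink amplitude default is chosen so that the frontal projection (150 µV)
strictly exceeds the ±80 µV rule even when a blink peak lands inside the
200-ms baseline window, where baseline subtraction can absorb part of the
excursion; with weaker blinks an uncorrected blink could evade rejection,
which would make the artifact-handling guarantees vacuous.

Task pacing (inter-trial interval 2.5–3.5 s, uniform) is a configurable
default, not an inferred quantity; onsets snap to the 250 Hz grid so
epochs stay sample-aligned after decimation.

Questionnaire scores come from a Gaussian copula: latent eFAA ranks are
mapped to normal scores, correlated normals are drawn at the Pearson value
\(2\sin(\pi\rho/6)\) that yields the target Spearman rho, and pushed
through skewed count marginals — BDI as a rounded Gamma(1.2) scaled so
~15% of subjects reach the 10-point cut-off (the published quantities are
the cut-off and the group split, not full distributions, so the marginal
shapes are modelling choices); RPQ forced to 0 for the non-symptomatic
group (which is *defined* by reporting no symptoms) and 1 + rounded Gamma
for the symptomatic group; PTA as Gamma hours truncated below the 24-h
mild-TBI criterion. Integer ties and the structural RPQ zeros attenuate
rank correlations, so the ±0.05 recovery contract is asserted for the BDI
coupling; for RPQ and PTA the tests assert sign and strict monotonicity in
the target.

**The fast path.** `simulate_scores_table()` produces the subject-level
score table directly from the latent layer, adding per-cell Gaussian
measurement noise with SD 0.012 — the value measured as the SD of
recovered-minus-target cell FAA when the full 16-block EEG chain runs at
the default noise and blink settings. Statistical calibration studies
(type-I error over 1000 seeds, coupling recovery at n = 500) use this
path; the EEG stage's fidelity is established separately by the
deterministic signal-chain tests, so re-synthesising gigabytes of EEG per
seed would add no information.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: no event-related potentials, reaction
times or error trials; no volume-conduction head model (blink propagation
is a single fixed factor, alpha sources are electrode-local); a fixed
10 Hz alpha peak with no individual alpha-frequency variation; stationary
noise; and alpha amplitude constant within condition rather than
fluctuating trial to trial. Conclusions about pipeline *correctness*
transfer to real data; conclusions about statistical *power* do so only to
the extent that real effect and noise scales match the configured ones.

## Problem sizes used in the test suite

Unit and acceptance tests run the EEG chain on reduced tasks (4 blocks of
8–16 trials, ~2–3 min of signal per subject; single subjects or 6-subject
cohorts) — the chain is linear per sample, so fidelity established at this
scale transfers to the full 16 × 64 task, and the full-scale chain was run
during development to measure the residual error that
`simulate_scores_table()` models. Calibration suites use the latent layer:
1000 null cohorts of 8 subjects per group for type-I error, 100 random
small designs for the ANOVA oracle, and a 500-subject cohort for coupling
recovery. The complete suite runs in a few minutes on one CPU.

## Known limitations

* The mixed ANOVA supports one between factor and at most two two-level
  within factors — the designs used here — not general factorial designs.
* Ocular correction is single-coefficient regression; it removes what
  correlates linearly with the EOG and nothing else.
* The BrainVision reader covers the multiplexed IEEE float32 and INT_16
  dialects only; EDF/BDF/FIF are out of scope.
* Published group-level F statistics from the clinical cohort are not
  reproducible targets: the underlying data are unavailable. What the
  package guarantees instead is the exact arithmetic of the published
  summary (`reproduce_table1()`), calibrated inference on synthetic truth,
  and exact recovery of configured effects through the signal chain.
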