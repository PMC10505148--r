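---
title: "Measuring and simulating speech-production variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and simulating speech-production variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechvar)
```

## The problem

Motor abnormalities are among the earliest signs in people at clinical high
risk (CHR) for psychosis. Speech articulation is a fast, precisely timed motor
behavior, so degraded speech-motor control should show up as *less consistent*
production: more variable stop-consonant voice-onset-times (VOT), more
variable vowel durations, more variable speaking rates. `speechvar` implements
the full measurement and inference layer for such studies. It deliberately
starts downstream of the audio: its inputs are time-aligned segment intervals
(Praat TextGrids from forced alignment, DDK segmentation, or VOT/formant
trackers), because that is the level at which the analysis is defined and at
which results can be made exactly reproducible.

## The measure battery

All variability measures are built on the coefficient of variation,

$$\mathrm{CoV} = \frac{\text{sample SD (n-1)}}{\text{mean}},$$

a scale-free quantity, so a participant who is uniformly slower is not
penalized. The battery and its task applicability
(`measure_applicability()`):

| measure | AMR | SMR | READ | SPONT |
|---|---|---|---|---|
| voiceless VOT CoV | x | x | x | x |
| voiced VOT CoV | | | x | x |
| speech-rate CoV | x | x | x | x |
| vowel-duration CoV | x | x | x | x |
| formant dispersion 20% | x | x | x | x |
| dispersion change 20–50% | x | x | x | x |
| vowel-category overlap | | | x | x |
| syllable-duration CoV | x | x | | |
| intersyllable-duration CoV | x | x | | |
| pause rate | | | x | x |

Definitional choices that the battery pins down:

- **Token selection.** VOT tokens are syllable-initial stops immediately
  followed by a vowel. Syllable-initiality uses a proxy rule (word-initial, or
  preceded by a vowel or silence), since the upstream aligner's dictionary
  syllabification is not available at the segment level; this is an
  onset-maximization approximation and may differ from dictionary
  syllabification for some medial clusters. VOT comes from the `vot_s`
  attribute when present and otherwise from the stop interval's duration
  (DDK-style segmentations use the consonant interval as the VOT proxy).
  Voiced tokens with non-positive VOT (prevoicing) are excluded — the CoV of a
  signed quantity is not interpretable — and counted. Vowel-duration and
  formant measures use primary-stressed vowels; in the DDK tasks every
  repeated CV syllable counts as stressed.
- **Phrases.** For read/spontaneous speech, the rate unit is the phrase: a
  maximal spoken interval between silences of **at least 150 ms**
  (inclusive — a 150 ms silence delimits). Sub-threshold silences are part of
  the phrase and its duration. Leading/trailing silence belongs to no phrase.
- **Pause rate** is the count of internal silences ≥ 150 ms divided by the
  total sample duration. This normalization is a package decision (the count
  could also be normalized per phrase or per syllable); per-second
  normalization yields values of the expected sub-1 magnitude and is invariant
  to sample length.
- **Formant dispersion** is the mean Euclidean distance of vowel tokens from
  their (F1, F2) centroid at the 20% timepoint; the 20→50% change is the
  signed difference of dispersions over tokens carrying both timepoints.
  **Overlap** is the percentage of tokens strictly closer to another
  category's centroid than to their own, ties resolving to the own category.
  These are reconstructions of standard vowel-space statistics chosen to be
  exactly testable (translation-invariant, homogeneous of degree one,
  bounded).
- **Log transform.** Variability measures are right-skewed with a floor at 0,
  so analyses use natural logs. Exact zeros (overlap, pause measures) become
  `log(eps)` with `eps = 1e-3` on the measure's natural scale; the signed
  dispersion-change measure keeps `NA` when negative. `eps` is recorded in the
  run log.
- **Token floor.** CoV/dispersion measures require `min_n = 5` tokens
  (configurable); below it the cell is missing with reason
  `insufficient_tokens` rather than a noisy value.

## The inference layer

Each measure × task cell is analyzed with OLS on the log measure with a CHR
indicator. For *durational* measures (VOT, vowel, syllable, intersyllable
CoVs) the participant's averaged speech rate for that task enters as a
covariate, so that rate differences between groups cannot masquerade as
duration-variability differences; the rate-CoV measure itself is not
rate-adjusted. α = 0.05 throughout with no multiple-comparison correction —
that mirrors the analysis protocol this package operationalizes, not best
practice, and the validity grid is *gated*: correlations with clinical/motor
covariates (SIPS totals, item G3, per-hand finger-tapping CoV over the first
three 10-s trials, a risk-calculator score) are computed within the CHR group
only for measures whose group test is significant.

The post-hoc power analytics use the Fisher-z approximation with the usual
+3 small-sample correction, pinned to two-sided α = 0.05 and power 0.80:
this convention reproduces both of its reference values (a required N of 56
at r = 0.37, and a minimal detectable r of ≈ 0.39 at n = 50), whereas a
power-0.9 convention does not; both are available through the `power`
argument.

The in-person/remote comparison refits the group model per modality stratum
and adds a full-sample group × modality interaction model — the exact post-hoc
model is a package decision, as stratified re-analysis protocols are usually
underspecified. Demographic confound checks regress each demographic on the
measure (OLS for continuous, logistic for categorical, multi-level factors
binarized majority-vs-rest), and the classification analysis is a univariate
logistic model scored by leave-one-out accuracy.

## The synthetic cohort generator

Nothing in the generator is fit to data at run time; it is a *stated world*
whose parameters are the published group-level anchors
(`default_group_params()`): per measure × task, the target mean and
between-participant SD of each group's measure distribution, e.g. AMR
voiceless-VOT CoV 0.31 (0.09) CHR vs 0.27 (0.10) HC. Structure follows the
study design: pools of 55 CHR / 65 HC participants with per-task subsamples
(51/53 DDK, 55/65 read, 50/50 spontaneous), 12 AMR trials × 15 CV syllables
(two trials per stop), 20 SMR trials × 30 syllables, a ~9-phrase read passage
and a ~2-minute spontaneous sample; an in-person/remote split matching the
cohort's (26/30 CHR, 44/22 HC).

Key generative decisions:

- **Between-participant law.** A participant's target CoV is log-normal with
  the anchor mean and SD (log-normality keeps targets positive and matches
  the right skew that motivates the log transform); Hz-scale and signed
  measures use a normal law.
- **Exact realization.** Token durations are drawn log-normal and their log
  deviations rescaled by one-dimensional root finding so the *realized* sample
  CoV equals the participant's target exactly (`target_cov_values()`). This
  makes the measure-level and segment-level generation provably equivalent for
  the CoV and rate measures (a property asserted by a test), so Monte-Carlo
  calibration studies can run at measure level without changing their meaning.
  Consequences worth knowing: AMR/SMR vowel and intersyllable durations are
  scaled per trial to meet the trial's rate budget, which inflates their
  realized CoV mildly above target (~5–10%); spontaneous-speech rate-CoV
  targets are capped at 1.2 (larger values are not physically realizable with
  positive phrase rates in a bounded recording); dispersion-change and overlap
  are emergent at segment level rather than exactly targeted.
- **Latent motor factor.** Each participant carries a standard-normal latent
  factor z. Speech-measure deviates load on z with `speech_loading` (default
  0.6 — a moderate shared motor factor; measures are conditionally independent
  given z), and the tapping/SIPS/risk deviates correlate with z at `rho`
  (default 0.37, the anchor correlation between tapping and negative
  symptoms reported in earlier CHR work). The implied speech–tapping
  correlation is `speech_loading * rho`; setting `speech_loading = 1` makes it
  exactly `rho`, which is how the latent-recovery calibration is run.
- **Tapping counts** are three integer taps-per-10-s trials per hand,
  constructed so the realized 3-trial CoV matches its target as closely as
  integer counts allow (best of a 27-point neighborhood).
- **Risk scores** are mapped monotonically into the observed 0.8–10.1% range
  via a probit transform; control participants get floor-level symptom scores
  and no risk score.
- **Remote effect.** `remote_inflation` multiplies the between-participant SD
  for remotely-tested controls. It defaults to 1 (off) because the anchor SDs
  are whole-sample values; modality analyses switch it on explicitly.
- **Determinism.** Every participant draws from an own seeded substream keyed
  by (group, within-group index), so cohorts are byte-reproducible from
  (config, seed) and resizing one group never perturbs the other.

What a green simulation-based test does and does not establish: the generator
emulates segment timing statistics, formant clouds, and covariate structure,
not audio, phonotactics, alignment errors, or real between-measure correlation
structure (measures are conditionally independent given the latent factor —
the true joint structure across the ten measures is unknown). Calibration
results (type-I error, parameter recovery, qualitative group pattern) validate
the pipeline's statistics, not any clinical claim.

## Numerical and degenerate-input policy

- Half-open interval convention `[start_s, end_s)` in seconds; overlap and
  tiling checks use 1e-9–1e-6 s tolerances; TextGrid times are written with 17
  significant digits, which round-trips doubles exactly.
- CoV of fewer than `min_n` tokens, formant-less vowel sets, or single-category
  overlap produce typed missingness (`insufficient_tokens`, `no_formants`,
  `one_category`) that propagates through the measure table without aborting
  it.
- Regression cells need ≥ 3 participants per group; validity correlations ≥ 4
  complete pairs and non-degenerate variance; a constant rate covariate is
  dropped with a warning.
- Ties in the overlap measure (equidistant centroids) count as non-overlapping
  by decision; zero-length phrase candidates and empty trial windows are
  skipped with warnings.

## Known limitations

- The syllable-initiality proxy and the reconstructed vowel-space formulas may
  differ from dictionary-based or study-specific supplementary definitions.
- Syllable counts are vowel-nucleus counts; syllabic consonants are not
  recognized.
- The generator's read/spontaneous "passages" emulate token counts and timing,
  not real lexical content; voiced-VOT prevoicing is not simulated (all
  generated voiced stops are short-lag).
- Inference is deliberately plain OLS/Pearson at α = 0.05 — no mixed models,
  no multiple-testing correction — to match the protocol it reproduces.
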