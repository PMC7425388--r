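---
title: "Methods: coregistered eye-tracking and presaccadic EEG analysis of the noise pareidolia test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coregistered eye-tracking and presaccadic EEG analysis of the noise pareidolia test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nptfrp)
```

## The task and the measurements

The noise pareidolia test (NPT) presents a series of two-tone noise images,
a minority of which contain an embedded low-information (Mooney-style) face,
and asks for a forced face/no-face judgement on each. A face reported on a
faceless image is a *pareidolia* — an illusory percept that, in Parkinson's
disease, indexes susceptibility to visual hallucinations. Coregistering an
eye tracker with scalp EEG during the test yields two complementary
readouts:

* **Where and how long the eyes dwell.** Fixations are assigned to
  pre-drawn areas of interest (AOIs: one ellipse per embedded face, one or
  more polygons over salient noise patches), and five metrics summarise
  behaviour per AOI: first fixation duration (FFD, ms), total fixation
  duration (TFD, s), visit duration (VD, s), fixation count (FC) and visit
  count (VC). A *visit* (dwell) runs from the first fixation inside an AOI
  until gaze leaves it, including the saccades between in-AOI fixations.
  Metrics are computed separately for *early* search (stimulus onset to
  5 s) and *late* search (5 s to the verbal response).

* **What the cortex does before each saccade.** The presaccadic potential
  is a slow deflection that builds up over the ~200 ms before saccade
  onset. Epochs locked to saccade onset ([−200, +50) ms) are baseline
  corrected on [−200, −170) ms and summarised by the mean amplitude over
  [−100, −20) ms, separately for a frontal (F3, Fz, F4, FC1, FC2) and a
  parietal (P3, Pz, P4, PO3, PO4) electrode group; the final 20 ms are
  excluded to avoid the spike potential at saccade onset.

The patient recordings behind the original study are not publicly
deposited, so the package pairs every analysis stage with a synthetic
session generator that embeds known ground truth. The generator is
first-class, tested code: it defines the conditions under which every
quantitative guarantee of the pipeline is verified.

## Pipeline stages and their contracts

1. **Event detection** (`detect_events`): I-VT velocity-threshold
   segmentation. Angular velocity per inter-sample interval is computed
   from pixel displacement via the exact subtended-angle formula
   (`pixels_to_degrees`); intervals below 30°/s accrue to fixations,
   above to saccades; runs of invalid samples ≥ 50 ms become blinks;
   candidate fixations shorter than 60 ms are discarded. The 30°/s and
   60 ms defaults are conventional I-VT settings — vendor filter
   parameters for the original recordings are undisclosed, so these are
   explicit substitutes, not inferences.

2. **AOI metrics** (`compute_metrics`, `compute_visits`,
   `bin_early_late`): windows are half-open `[t0, t1)`. Events straddling
   a window edge contribute their in-window portion to duration metrics
   but are counted once, in the window containing their onset. This keeps
   durations conservative (early + late = total exactly) while keeping
   counts integral; both properties are asserted in the tests at 1e-9
   tolerance. FFD of an AOI never fixated is missing (`NA`), not zero, so
   averages are taken over visited AOIs only.

3. **Response scoring** (`classify_response`, `score_subject`, `dprime`):
   hits H = Face/(Face+Missed), false alarms F =
   Pareidolia/(Pareidolia+Noise), scored on available trials without
   imputation. Sensitivity uses the unequal-variance form
   d_a = sqrt(2/(1+s²))·(z(H) − s·z(F)) with configurable noise/signal SD
   ratio `s` (default 1, the classical d′): the original report adjusts
   for unequal noise-signal variance but does not print its formula or
   slope, so the slope is surfaced as a parameter rather than guessed.
   Extreme rates are handled by the log-linear correction (+0.5 per cell,
   +1 per denominator) — chosen over 1/(2N) clamping because one
   convention had to be fixed; it keeps d′ finite for every count
   configuration. Patients are dichotomised on the *original* paper-based
   NPT count (0–1 non-pareidolic, ≥2 pareidolic); the modified test's own
   score is never used for grouping.

4. **EEG conditioning** (`preprocess_eeg`): fixed order — average
   reference, 2–40 Hz band-pass, decimation to 500 Hz. The band-pass is a
   4th-order Butterworth *squared-magnitude* response applied spectrally
   on zero-padded FFTs. This realises exactly the amplitude response of a
   forward–backward (filtfilt) pass with strictly zero phase — the slow
   presaccadic ramp must not be shifted in time — and is numerically
   robust where high-order recursive band-passes with narrow normalised
   bands (2–40 Hz at 2 kHz) are ill-conditioned; in testing, a recursive
   transfer-function implementation broke linearity at the 1e-3 level,
   while the spectral form is linear to machine precision. ICA-based
   artefact removal is out of scope: `preprocess_eeg` accepts a pluggable
   cleaning hook (default identity), and artefact protection comes from
   the blink-exclusion rule and the ±80 µV epoch rejection.

5. **Valid-fixation selection and matching** (`select_valid_fixations`,
   `mahalanobis_match`): five inclusion rules — fixation duration within
   [200, 2000] ms (closed bounds; 199 ms is out, 200 ms is in), following
   saccade strictly < 80 ms, fixation onset ≥ 700 ms after stimulus onset,
   saccade onset at or before the response, and no blink overlapping
   ±300 ms around saccade onset. A saccade of exactly 4.0° classifies as
   *long* (the boundary convention had to be fixed somewhere; it is stated
   in the config docs). Outlier fixations are then removed by Mahalanobis
   distance over (saccade amplitude, fixation duration) against the
   pooled mean/covariance, cutting above the empirical 95th percentile.
   The distance is computed per subject by default (configurable to
   pooled): the original text is ambiguous about the pooling level, so
   both ship as switches with a documented default rather than a guess of
   original intent. The feature set is likewise configurable and logged.

6. **Epoching and amplitudes** (`extract_epochs`, `reject_artifacts`,
   `baseline_correct`, `mean_amplitude`, `match_trial_counts`,
   `grand_average`): all windows are half-open in samples; at 500 Hz an
   epoch holds exactly 125 samples and the −20 ms edge sample is excluded
   from the amplitude window, honouring the spike-potential guard.
   Rejection (any sample beyond ±80 µV on the analysed channels) runs
   before baseline correction. Within each subject, response categories
   with fewer than 50 epochs are excluded and the rest are subsampled
   (seeded, without replacement) to the smallest remaining count — the
   healthy-control pareidolia/missed exclusion seen in practice emerges
   from this rule rather than being hard-coded.

7. **Group statistics** (`rm_anova`, `manova_then_univariate`,
   `kruskal_dunn`, `power_sample_size`): the eye-tracking layer is a
   two-factor repeated-measures ANOVA (between: group; within: metric),
   fitted as the classical univariate `aov` with `Error(subject/within)`
   strata — exact under compound symmetry, which the generator's
   subject-intercept model satisfies — with least-square means ± SEM via
   `emmeans` and Holm–Šidák step-down pairwise comparisons when the
   interaction is significant. The EEG layer takes frontal and parietal
   amplitudes as joint DVs in a MANOVA (Wilks' λ), with univariate
   follow-ups only on significance, Mahalanobis outlier removal
   (χ² cutoff, p = 0.001), a moderate-correlation screen (r in
   [0.3, 0.6]; failure is a warning, not an abort, since no failure
   action is prescribed), Lilliefors-corrected KS normality checks, and an
   aligned-rank-transform ANOVA as the nonparametric fallback (switchable
   to plain rank transform). Behavioural counts use Kruskal–Wallis with
   Dunn's z-tests for unequal groups.

## The design-stage power computation

The sample-size routine inverts the exact noncentral-F power of a balanced
one-way k-group ANOVA. A single "minimum detectable mean level" of 0.3
does not uniquely fix three group means, so the convention is explicit:
by default the spread is the **maximum pairwise mean difference with the
remaining group at the midpoint** (means −0.15, 0, +0.15), the
configuration with the smallest noncentrality for that spread and hence
the conservative design choice. With residual SD 0.15, α = 0.05 and target
power 0.95 this yields n = 9 per group (power 0.955; n = 8 gives 0.924).
The alternative "extreme" convention (0, 0, 0.3) would give n = 7. The
returned n is cross-validated by Monte-Carlo simulation of the ANOVA at
that size (`mc_anova_power`), and the analytic curve is checked against
`stats::power.anova.test` in the test suite.

## What the generator emulates — and what it does not

`simulate_study` builds an 80-image session (20 embedded faces) per
subject by default, with a 2-s fixation cross between stimuli, 120 Hz gaze
sampling and 700 × 700 px stimuli viewed at 80 cm (pixel pitch
0.2766 mm/px, a 24-inch 1920-px-wide display; the configured resolution is
metadata only).

* **Stimuli.** AOIs are placed in disjoint cells of a 3×3 grid: one
  off-centre target ellipse on face images (never the central cell,
  echoing the peripheral placement of the real targets), one to three
  star-shaped noise polygons everywhere. Disjointness and in-bounds
  placement are by construction and verified against a rasterised overlap
  oracle. No photorealistic Mooney rendering is attempted.

* **Behaviour.** Responses are Bernoulli draws from per-group hit and
  pareidolia rates; default rates give the qualitative group pattern
  (controls accurate, pareidolic patients reporting faces on ~40% of
  noise images). Response times are log-normal around group medians of
  8.9 s (controls) and 9.2 s (patients). Gaze alternates fixations
  (Gaussian durations per group profile) with saccades whose amplitudes
  mix short (1–3.5°) and long (4.5–12°) moves and whose durations grow
  with amplitude (18 + 2.2 ms/°, capped at 75 ms) so that every saccade
  clears the I-VT threshold at 120 Hz. Fixational jitter is 1.5 px SD;
  with jitter and blinks disabled the re-segmented event counts equal the
  ground truth exactly, and the tests assert ≥95% fixation recovery under
  realistic jitter and blinks. Dwell parameters are free simulation
  knobs, not estimates of the published group tables: the original paper
  gives no generative description of pareidolic gaze paths.

* **EEG.** Signal = 1/f background (spectrally shaped white noise,
  exponent 1, per-channel SD 5 µV by default) + a linear presaccadic ramp
  per saccade on the targeted electrode group + a brief Gaussian spike at
  onset + half-cosine blink artefacts (150 µV, 200 ms) on frontal
  channels. The ramp rises from 0 at −200 ms to its peak at −20 ms. The
  configured effect size is the *measured* amplitude — the
  baseline-corrected mean the pipeline reports — which for the linear
  ramp is 25/36 of the −20 ms peak; the generator therefore scales the
  peak to 36/25 of the configured value, making the closed-form
  recoverability exact at zero noise (asserted to float tolerance).
  Saccade onsets are aligned to the EEG sample grid so this exactness is
  well-defined. The generator emits data at the 500 Hz analysis rate,
  standing in for *conditioned* recordings: re-running the average
  reference on 10 channels carrying a 5-channel effect would smear half
  the ramp onto the other group, which is a property of montage algebra,
  not of the analysis under test. The conditioning chain is verified on
  its own sinusoid and linearity probes instead. No volume-conduction
  head model and no saccade main-sequence modelling are attempted.

Default effect amplitudes mirror the qualitative published pattern:
positive parietal activity for faces (+0.6 µV), negative parietal
activity for noise (−0.93/−0.41/−0.38 µV for HC/PDnP/PDP), and a frontal
pareidolia contrast of +1.0 µV (PDP) versus −0.3 µV (PDnP). The recovery
tests embed these, add 5 µV noise, and require the seed-averaged
recovered amplitudes within ±0.2 µV with the PDP−PDnP contrast sign
correct in every seed.

Passing these tests shows the pipeline is *internally correct* — it
recovers what was embedded, conserves what must be conserved, and keeps
nominal error rates. It does not show that real Parkinson's data would
reproduce the published group effects: the generator has no oculomotor
pathology model, no cognitive covariates, and no real scalp topography.

## Problem sizes and numerical choices

The test suite and the acceptance checks run at deliberately modest
sizes, chosen as the smallest scales at which each property is
informative: filter-oracle equivalence on 50 synthetic sessions
(~600–1000 candidate fixations each, compared exactly); amplitude
recovery on 20 seeds × 200 trials per cell; null calibration of the
RM-ANOVA interaction, the MANOVA group test and Kruskal–Wallis on 500
null simulations each (rejection rates required within 0.05 ± 0.02);
Mahalanobis percentile behaviour on 10 000 bivariate-normal samples. The
analysis workflow under `analysis/` uses a reduced cohort (6/5/5 subjects,
40 images) for the same reason, and scales linearly if the full design
(12/11/10, 80 images) is configured.

Other numerical conventions, collected: all windows half-open; times in
ms on a session clock with per-trial onsets (explicit onset metadata
replaces hardware sync); epoch sample index = `round(t·fs/1000)`;
coordinates origin top-left, y down, px; seeded reproducibility
throughout (every stochastic stage derives child seeds from one master
seed, and reruns are bit-identical, which the pipeline test asserts on
the output files).

## Known limitations

* EEG I/O is a headered CSV matrix; EDF/BDF ingestion is not implemented.
* ICA artefact removal is a hook, not an implementation.
* The RM-ANOVA assumes compound symmetry (no sphericity correction is
  applied); this is exact for the generator and standard for the two- and
  three-level within factors used here.
* Smooth pursuit is not classified; pursuit segments would be absorbed
  into fixations or saccades depending on velocity.
* The d′ variance-ratio slope is a free parameter; published values
  cannot be recomputed without the original trial data.
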