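---
title: "ECG pain biomarkers: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG pain biomarkers: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cardiopain` implements an end-to-end analysis for objective pain
assessment from the ECG: a synthetic study generator with known autonomic
ground truth, a multi-domain biomarker battery, a dual-layer
classification-then-regression cascade, and a multi-method explainability
and agreement suite. This vignette is the package's own account of the
science behind each stage — the assumptions, the tunable parameters, and
the decisions taken where the design was genuinely open.

## 1. The physiological model behind the generator

Acute nociceptive input activates the sympathetic branch of the autonomic
nervous system and withdraws vagal tone. The generator encodes the four
consequences that are visible in a single-lead ECG as explicit,
recoverable effect sizes (`autonomic_effect()`):

| parameter | unit | default | meaning |
|---|---|---|---|
| `baseline_hr_bpm` | bpm | 70 | resting heart rate |
| `hr_gain_bpm_per_pain_unit` | bpm / CoVAS unit | 0.25 | HR rise with momentary pain |
| `baseline_sdnn_ms` | ms | 50 | resting beat-to-beat variability |
| `sdnn_suppression_frac_at_max_pain` | — | 0.5 | fraction of SDNN lost at CoVAS 100 |
| `amplitude_gain_frac_at_max_pain` | — | 0.3 | fractional ECG amplitude rise at CoVAS 100 |
| `lfhf_baseline`, `lfhf_gain` | — | 1.5, 1.5 | sympathovagal balance and its shift |
| `covas_noise_sd` | CoVAS units | 3 | trial-to-trial rating noise |
| `hr_drift_sd_bpm` | bpm | 3 | slow stimulus-independent HR wander |
| `amp_drift_sd_frac` | — | 0.05 | slow amplitude wander |

Defaults are chosen to be physiologically plausible for healthy adults
under tonic heat pain: a rise of ~20 bpm and an SDNN reduction of ~40% at
the strongest rating, with resting SDNN of 50 ms and LF/HF near 1.5. The
two *drift* terms deserve emphasis: they place slow (VLF-band, ~0.01 Hz)
stimulus-independent wander on heart rate and ECG amplitude, emulating
thermoregulation, posture and electrode effects. Without them every rest
window would be statistically identical and the classification task would
be trivially separable; with them, mild-pain windows genuinely overlap the
rest distribution, which is what recorded pain datasets look like.

Beat-to-beat variability is synthesized spectrally: two Gaussian spectral
lobes (LF ≈ 0.10 Hz, HF ≈ 0.25 Hz) with random phases are inverse-FFT'd
into a modulation series whose lobe powers sit in the requested LF/HF
ratio and whose variance is scaled to the SDNN target. Beat times are then
accumulated interval by interval, which gives direct control of the mean
rate, and the ECG is drawn as five Gaussian bumps (P, Q, R, S, T) per
beat. The whole beat is scaled by the amplitude factor so that
peak-to-peak amplitude is exactly linear in it.

The session layout follows the tonic heat-pain paradigm: five temperature
levels, each applied eight times for 10 s in randomized order with rests
drawn uniformly from 20–30 s. The per-level CoVAS plateau is a linear map
(0, 15, 35, 60, 85 by default) spanning the no-pain/mild/moderate/severe
strata, with truncated Gaussian rating noise; the lowest level is
non-painful and maps to a rating of exactly 0, and CoVAS is exactly 0
whenever no stimulus is applied, matching the labeling rule below.

**What the generator does not emulate:** multi-lead morphology, ectopy and
artifact, respiratory sinus arrhythmia as an explicit respiration channel,
thermode physics, habituation/sensitization across repetitions, and
between-subject heterogeneity of effect *direction*. Tests passing on this
generator therefore demonstrate that the pipeline recovers known autonomic
structure from realistic single-lead signals — not that any particular
clinical accuracy will be attained on recorded data.

## 2. Windowing and labels

Analysis windows are stimulus-aligned by default: one window per stimulus
covering its 10-s application, plus one 10-s baseline window ending at the
onset. A fixed-length mode (1000 samples, configurable stride) is also
provided: both conventions are defensible units for window-level ECG
statistics, and keeping both as config keys makes the choice a one-line
change. Stimulus-aligned windows are the default because they carry the
CoVAS semantics needed for labels and strata.

A window's rating is reduced to a scalar by the **mean** CoVAS over the
window (a continuous rating's central tendency is the least surprising
reduction; `max` is available), and the binary label follows the rule
*no pain ⇔ CoVAS = 0*, *pain ⇔ CoVAS > 0*. Intervals are half-open
[t, t + 10 s) with 0-based sample indexing. A stimulus closer than one
window length to the record start loses its baseline window with a
warning.

## 3. The biomarker battery

Each window yields 19 named features. Conventions that matter:

- RMS and power are computed on the raw, uncentered voltage
  (`power = rms²` exactly); kurtosis is Fisher excess and skewness the
  standardized third moment, both in uncorrected population form — the
  dominant convention in HRV/biosignal toolboxes. SDNN uses the sample
  (n − 1) standard deviation. pNN50 counts successive differences
  **strictly** greater than 50 ms.
- R peaks come from a Pan–Tompkins-style detector (5–25 Hz band-pass,
  derivative-energy envelope, adaptive threshold at 20% of the 99.5th
  envelope percentile, 250 ms refractory period) with peak refinement on
  the raw signal; it is invariant to constant voltage offsets. Fewer than
  two detectable beats flags the HRV cells *missing*, never zero.
- Frequency-domain HRV interpolates the RR tachogram to an even 4 Hz grid
  (cubic spline) — Welch's method is undefined on unevenly sampled data
  and 4 Hz is the field standard — then averages Hann-windowed 60-s
  segments with 50% overlap. Band powers are trapezoidal integrals over
  VLF 0.003–0.04, LF 0.04–0.15 and HF 0.15–0.4 Hz. On records shorter
  than one segment the segment shrinks to the record with a warning. When
  a band contains a single resolvable frequency bin (a 10-s window leaves
  LF with one bin), the power is the bin value times the bin width rather
  than an empty integral.
- VLF power over a 10-s window is physically near-meaningless (the period
  exceeds the window); it is computed for completeness of the battery and
  is typically zero-variance there, in which case standardization flags
  it and recursive feature elimination discards it immediately.
- Geometric HRV uses the conventional 1000/128 ≈ 7.8125 ms histogram bin.
  TINN is the base of the least-squares best-fit triangle with its apex
  fixed at the modal bin, searched over bin-center candidates padded 25
  bins beyond the observed range; if all intervals fall in one bin the
  triangular index is 1 and TINN is one bin width.

No preliminary feature exclusion is applied: the full battery is computed
and an exclusion list is a config choice, since window-level informativeness
depends on the recording conditions.

## 4. The cascade

The dual-layer design mirrors clinical reasoning — decide *whether* pain
is present, then *how much*. Pipeline order matters for leakage: the
train/test split (stratified by label at `test_fraction = 0.2`) happens
first; the scaler (median imputation, then centering/scaling) and the
recursive feature elimination are fit on the training split only.

Open choices and the defaults taken:

- **Forest hyperparameters** (unstated in most applied work): 100 trees,
  unlimited depth, `sqrt(p)` feature subsampling, all seeded. `rfe_k = 10`
  of the 19 features by default.
- **Split unit**: `by_window` by default (matching a "20% of total data"
  reading); `by_session` holds out whole sessions and is recommended when
  sessions proxy subjects, because window-level splits share slow drift
  between train and test.
- **Regressor gate**: the intensity regressor trains on rows with *actual*
  CoVAS > 0 by default; a `classifier` gate (train on rows the fitted
  classifier calls pain) is available, since either reading is plausible
  when a cascade is described loosely.
- **Decision threshold** 0.5, with the tie falling to *pain*
  (probability ≥ threshold), configurable for sensitivity/specificity
  trade-offs.

Predicted intensity is clipped to [0, 100] and is exactly 0 for any row
classified no-pain — the cascade contract asserted by the tests.

## 5. Explainability

**Shapley values.** The attribution uses the background-replacement value
function: f(S) is the model applied to the explained row with features
outside S replaced by background-row values, averaged over the background
set. The background is a seeded subsample of the training split (capped at
~20–100 rows): the value function needs a reference distribution, and the
training distribution is the least arbitrary one. Two independent routes
are implemented: exact subset enumeration (exponential, capped at 12
features) and a per-leaf combinatorial tree-path algorithm that exploits
the fact that a leaf's reachability under any composite row depends only
on which path features must come from the row versus the background. Both
compute the same mathematical object; their agreement (within 1e−4, in
practice machine precision) is the package's own correctness oracle, and
efficiency (base + Σφ = output) holds to 1e−6 by construction. Interaction
values use the pairwise Shapley interaction index by enumeration, with
main effects on the diagonal so that matrix rows sum to φ.

**Importance measures.** Gini importance is the forest's normalized mean
decrease in impurity. Permutation importance shuffles one feature at a
time *within the evaluation split* (that is what "decrease in model
performance" means operationally), scoring accuracy for classification and
R² for regression, repeated 100 times; reports show mean ± SD.

**PDP/ICE.** The partial dependence expectation over the complement
features is taken empirically over the observed rows (the standard
marginalization; the joint-distribution expectation is not identifiable
from a fitted model alone), so PD is exactly the columnwise mean of the
ICE matrix. Grids default to 50 points between the 1st and 99th
percentile. ICE phenotype discovery centers each curve at its leftmost
grid value — clustering response *shapes*, not offsets — and applies
seeded k-means with k = 3 by default. The clustering method is a declared
reconstruction: centroid clustering of standardized ICE curves is the
simplest procedure consistent with reporting "distinct response
phenotypes", but it is not a reproduction of any specific published
procedure. Identical curves collapse to a single effective cluster with
zero dispersion rather than erroring.

**Global surrogate.** A CART tree of depth ≤ 5 (cp = 0, minimal split
sizes, no cross-validation pruning) is fit to the model's own predictions;
fidelity is agreement with the model on a held-out 30% of rows, and leaves
are exported as `IF … AND … THEN …` rules.

## 6. Evaluation

Pain is the positive class everywhere. Ratios with zero denominators are
reported missing, never zero. ROC AUC is the rank statistic with half
credit for ties; PR AUC is average precision; confidence intervals use a
stratified percentile bootstrap (2000 resamples by default) because a CI
method is rarely stated alongside reported intervals. Regression metrics
flag MAPE missing when any actual value is zero, and tolerance bands use
closed boundaries. Severity strata are (0, 30], (30, 70], (70, 100] with
actual CoVAS 0 as the no-pain stratum; per-stratum precision contrasts the
stratum's true positives against false alarms from the no-pain stratum,
which is the cleanest way to give "precision" a per-stratum meaning.
Bland–Altman uses the sample SD and the fixed 1.96 multiplier, with
proportional bias as the Pearson correlation of pairwise means and
differences; degenerate inputs (identical predictions) collapse the limits
and flag the correlation undefined.

## 7. Numerical and testing choices

- All randomness flows from one integer seed through a counter-based
  stream-splitting helper; every stage (session generation, splits, forest
  fits, bootstrap, permutation, k-means) derives its own stream, so a full
  run is byte-reproducible from the single seed.
- Problem sizes in the test-suite and acceptance script — 2–3 sessions of
  ~24 min each (240 windows), 50-window recovery regressions, 50-seed
  coverage simulations, 30–100-tree forests — are chosen so that every
  statistical check has adequate power while the whole suite stays quick
  to iterate on.
- The worked hand-check for the limits of agreement uses the exact sample
  SD of the differences (−2, 2, −1), namely 2.081666; carrying a
  3-decimal intermediate instead shifts the limits by ~0.001, which is why
  the frozen expected values are −4.4134 and 3.7467.
- The importance-convergence check (Gini vs permutation vs mean |φ|) uses
  two strongly modulated biomarker axes plus two pure-noise columns.
  Redundant collinear panels are exactly where permutation importance is
  known to disperse credit (permuting one of several correlated carriers
  of the same signal barely hurts the model), and with many noise features
  a rank correlation is dominated by arbitrary orderings within the noise
  floor — so method convergence is asserted on a panel where each
  informative feature is genuinely load-bearing and the comparison is
  meaningful.
- The null-effect negative control keeps non-zero CoVAS *labels* (subjects
  still rate the stimuli) while zeroing every physiological gain, so any
  above-chance accuracy would indicate label leakage through the feature
  layer rather than real signal.

## 8. Known limitations

Single-lead Gaussian-bump morphology cannot probe morphology-specific
detectors; the R-peak detector is validated against generator ground truth
rather than against annotated clinical recordings; VLF features are
uninformative at the default window length; severity-stratified precision
depends on the no-pain false-alarm convention described above; and the
synthetic study's effect sizes, while plausible, are not fit to any
recorded dataset — conclusions about absolute clinical performance require
real recordings ingested via `ingest_sessions()`.
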