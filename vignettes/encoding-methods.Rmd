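---
title: "Encoding models of facial-emotion features in intracranial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models of facial-emotion features in intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ieegencode)
```

## The scientific problem

How does the brain's representation of facial emotion develop? One way to
ask this with intracranial recordings is to model the high-frequency
broadband (HFB, 110–140 Hz) amplitude of each electrode contact as a linear
function of the facial-emotion content of a naturalistic movie, and compare
the fitted models across participants of different ages. The quantities of
interest are (a) the cross-validated prediction accuracy of the model —
does this cortical site encode facial-emotion information at all? — and
(b) the model weights — *which* emotion features drive the site, and do the
weights of socially complex emotions (guilt, embarrassment, pride, envy)
grow with age relative to basic ones (joy, sadness, fear, anger, disgust,
surprise)?

Patient recordings cannot be redistributed, so the package pairs the full
analysis pipeline with a synthetic-cohort generator whose ground truth is
known. Every stage of the analysis can therefore be validated end to end:
the generator writes the answer, the pipeline must recover it.

## The generative model

A simulated session is a 13-block movie (30 s blocks alternating music and
speech; the fifth music block contains no faces and is flagged
feature-absent). Facial-emotion features are 48 per-frame scores in
[0, 1]; the simulator draws them as smoothed Gaussian noise mapped through
the normal CDF, giving smooth, exactly bounded traces with a 2 s
autocorrelation length on the 2 Hz analysis grid (`generate_feature_timecourses`).

The binned HFB response of a contact follows the lagged linear model

y(t) = Σ_f Σ_l w[f, l] · x_f(t − lag_l) + ε,  lags = 0, 0.5, 1 s,

with i.i.d. Gaussian noise (`synthesize_binned_hfb`). Lags never cross
block boundaries: blocks are separate epochs and lagged samples before a
block's start are zero.

`generate_ground_truth` supplies the true `[48 × 3]` weight matrix in two
flavours:

* **independent** (default): every coefficient i.i.d. normal — maximally
  unstructured, used for the cohort simulations;
* **lag-coherent** (`lag_coherent = TRUE`): one exponential effect size and
  one sign per feature, modulated by a smooth positive lag profile. This is
  the physiologically sensible structure for a temporal response function —
  a feature that raises broadband amplitude at lag 0 does not flip to
  suppressing it half a second later, and effect sizes across features are
  sparse rather than uniform. It is the right truth for parameter-recovery
  checks, which need genuine between-feature contrast in the pooled
  absolute weights.

`generate_cohort` scales this up to a study-shaped cohort (11 children aged
5–10, 31 post-childhood individuals aged 13–55, DLPFC and pSTC coverage
mirroring the study's layout) with two built-in effects whose recovery the
tests check: complex-emotion weights grow linearly with age, and childhood
DLPFC weights are exactly zero — a known null for the group statistics.

For testing the signal chain, `synthesize_raw_signal` inverts
preprocessing: a 110–140 Hz noise carrier is amplitude-modulated by the
*squared* target envelope (the chain square-root-transforms extracted
amplitude), plus an optional 50 Hz line component and a pink-noise floor.

## Preprocessing

`preprocess_session` runs the fixed chain: 50 Hz notch (zero-phase
2nd-order Butterworth band-stop, Q = 30) → common average reference over
good channels → 110–140 Hz band-pass (4th-order Butterworth, zero-phase)
with Hilbert analytic amplitude → per-block epoching with a 0.2 s
pre-stimulus window → resampling to 400 Hz → square-root transform →
z-scoring against the block's own baseline.

Two numerical choices deserve a note:

* **Resampling.** The polyphase resampler in the `signal` package has a
  measurable DC-gain error (~7 %) and an edge transient that would
  contaminate the short baseline window, so the package uses its own
  anti-aliased resampler: reflect-padding, a zero-phase 4th-order
  Butterworth low-pass at 0.9 × the target Nyquist, and evaluation on the
  target grid by linear interpolation (`resample_padded`, applied to the
  smooth amplitude envelope, not to the raw carrier).
* **Baseline scale.** Each block is z-scored by statistics estimated from
  only 0.2 s of baseline — a handful of independent envelope samples at the
  ~30 Hz envelope bandwidth. Every block therefore carries a small random
  affine distortion. This is inherent to the published chain, and it is why
  the package's round-trip validation scores envelope recovery per block
  (each block is an independently normalized epoch) rather than across the
  concatenated recording.

## Design and encoding

`build_lagged_design` stacks each feature-present block's `[60 × 48]`
feature matrix with its 0.5 s and 1 s shifted copies, lag-major, giving
`[720 × 144]` per session. `bin_response` averages the 400 Hz epochs into
the matching 0.5 s bins, and `concatenate_contacts` stacks all contacts of
an area into a single regression problem sharing one weight vector.

`cv_evaluate` fits ridge regression (closed form, via Cholesky of the
centered normal equations) with 5-fold cross-validation; blocks are
round-robined into contiguous folds so folds never split a block.
Prediction accuracy is the mean held-out Pearson r. One penalty serves the
whole study: `select_global_lambda` scans a 20-value grid log-spaced over
10–10000 and keeps the value maximizing the unweighted mean accuracy over
all participant × area × condition datasets. `cv_grid` makes the scan cheap
by solving every penalty from a single eigendecomposition per fold.

## Inference

* `permutation_test` builds the accuracy null by shuffling feature time
  bins jointly across all 48 features (optionally within condition, or by
  per-block circular shifts) and re-running design + cross-validation each
  time; p = (#{|null| ≥ |observed|} + 1) / (n_perm + 1).
* `one_sample_t`, `paired_t`, `unpaired_t` wrap the standard t tests used
  at the group level (Student, equal-variance, for the group contrast);
  `voice_effect` contrasts the per-participant speech − music accuracy
  difference between groups.

## Weight analysis

`pool_fold_weights` reduces the `5 folds × 144` coefficients to 48
non-negative per-feature weights: the absolute coefficient values are
averaged over folds, then over the three lags (`collapse = "max"` keeps the
strongest lag instead). Taking absolute values first means a feature counts
equally whether it drives an HFB increase or decrease; it also means the
pooled weight of a truly null feature is positive noise, which is why
recovery checks compare *pooled* recovered against *pooled* true weights.
`weight_age_correlation` then correlates each feature's pooled weight with
age across participants (uncorrected two-sided p-values, features ranked by
r), with the complex/basic aggregates tested on the aggregated weights.
Participants enter this analysis only if their accuracy beats the
permutation null (`filter_significant_profiles`).

## Problem sizes

The packaged analysis scripts and validation suite run at desk scale, as
the package's own choice of problem size: the full 42-participant cohort
with 4 contacts per covered area and 199 permutation iterations in
`analysis/`, 200 null datasets × 199 permutations for the calibration
check, 20 seeds for the recovery simulations, and a 3-block, 4-contact
session for the raw-signal round trip. All sizes are arguments, so any of
them scales up by changing one number (e.g. `pipeline_config(n_perm = 5000)`).

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1, n_perm = 199)
res <- run_pipeline(cfg, out_dir = "results")
res$lambda                 # the single study-wide ridge penalty
head(res$encoding)         # per participant x area x condition accuracies
res$stats$pSTC_speech      # group t-tests against zero
head(res$weight_age$table) # features ranked by weight-age correlation
```
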