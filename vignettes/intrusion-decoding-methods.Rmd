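---
title: "Decoding transient memory intrusions from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding transient memory intrusions from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrudetect)
```

## The scientific problem

During a Think/No-Think (TNT) memory-suppression task, a cue that instructs
a participant *not* to recall an associated scene sometimes fails: the
memory intrudes into awareness, transiently, at an unpredictable moment
within the 3-second suppression cue. Participants can report *whether* a
trial contained an intrusion, but not *when*. `intrudetect` implements a
decoding strategy that localizes these events in time: classifiers are
trained on an independent attention task in which an unexpected image
captures attention reflexively at a known moment, and then generalized
across tasks to every timepoint of the suppression cue. The premise is that
an intruding memory recruits the same bottom-up attentional-capture
machinery as an unexpected visual stimulus, so a decoder of reflexive
capture doubles as a detector of involuntary recollection.

The pipeline has five stages:

1. **Within-task decoding** (`cv_auc_timecourse`, `cv_auc_timefreq`):
   per-timepoint random-forest classifiers (50 trees, balanced class
   weights, feature-wise standardization fit on the training split)
   discriminate intrusion from non-intrusion trials in the attention task
   under stratified 8-fold cross-validation, scored by AUC. A variant takes
   Morlet time-frequency power as features; `sensor_contrast` maps the
   condition difference across the montage with a max-statistic permutation
   correction.
2. **Cross-task temporal generalization** (`train_bank`, `generalize`): one
   classifier per attention timepoint in the 250-500 ms window (inclusive
   grid) is trained on *all* attention trials — no cross-validation,
   because testing happens on the other task — and applied to every
   timepoint of every TNT epoch, yielding an
   N~attention~ x N~TNT~ probability map per trial.
3. **Permutation-null event detection** (`build_null`, `binarize`): the
   bank is retrained 200 times with permuted training labels; the pooled
   null probabilities define a 95th-percentile threshold, and map entries
   strictly above it count as detected events.
4. **Memory-strength timecourses** (`smooth_strength`, `score_auc_matrix`):
   binary detections are convolved along TNT time with a unit-sum Gaussian
   kernel (FWHM 200 ms), giving a local event-density ("memory strength")
   series per trial. For each (attention, TNT) cell the across-trial AUC
   against the subjective reports is computed; the attention row with the
   best maximum is selected per participant and tested against chance at
   the group level with a cluster-based permutation test restricted to
   200-3000 ms.
5. **Regulation dynamics** (`intrusion_slope`, `decoded_slope`, `sif`,
   `slope_sif_correlation`, `label_states`, `state_contrast`): blockwise
   intrusion proportions give a per-participant Pearson-r "intrusion
   slope"; its decoded analogue uses only correctly classified timepoints
   and is compared with the baseline (-200-0 ms) slope; slopes are
   correlated (Spearman, bootstrap CI, permutation p) with
   suppression-induced forgetting (SIF = baseline recall - No-Think
   recall); and item-level state transitions (stable/regulated intrusive,
   stable/relapse non-intrusive, labeled from all future blocks of the same
   item) are contrasted with mixed models
   (`strength ~ state + (1 | participant) + (1 | item)`, REML,
   Satterthwaite t) under cluster permutation with labels shuffled within
   participant-by-block strata.

## Statistical machinery and its conventions

**AUC.** Computed from midranks, i.e. the normalized Mann-Whitney U with
ties counted 0.5 — exactly the pairwise-counting definition, and exactly
antisymmetric (`auc(s, y) + auc(-s, y) = 1`).

**Cluster-based permutation tests.** Pointwise t statistics are thresholded
at the two-sided p = 0.05 critical value (the cluster-forming threshold);
contiguous suprathreshold runs are clusters, their summed t is the cluster
mass, and each observed mass is compared with the permutation distribution
of the *maximum* mass (sign flips for one-sample/paired designs, label
shuffles — optionally within strata — for the general t-map engine).
Conventions: positive and negative clusters are formed separately and the
null uses the maximum absolute mass; the identity permutation is included,
`p = (1 + #{perm >= obs}) / (1 + n_perm)`, so p is never zero; zero-variance
timepoints get a clamped t of ±1e12 rather than ±Inf. Cluster adjacency is
1-D temporal contiguity. The defaults are 20000 permutations for t tests
and 1000 for the mixed-model contrast, which is much costlier per
permutation.

**Null-threshold scope.** The detection threshold is a single scalar per
participant and model, pooling null probabilities across permutations,
trials and both time axes. Pooling maximizes the null sample size and keeps
the detection rule exchangeable across timepoints. `build_null` can
estimate the pooled distribution from a seeded subset of TNT trials
(`max_trials`); the subset is an unbiased sample of the pooled null, and
the package's own checks verify that the resulting threshold still fires on
~5% of held-out null probabilities.

**Selection bias of the max-AUC rule.** Selecting the attention row with
the maximum report-AUC uses the reports themselves, which biases the
selected row's AUC upward under the null. This is a property of the
procedure, not a bug: the test suite measures it (the mean selected maximum
exceeds 0.5 under a full null while the unselected cell-wise mean stays at
chance within [0.48, 0.52]), and group-level inference against 0.5 should
therefore be read together with that measured bias.

**Ambiguities resolved.** Where the procedure leaves room for
interpretation the package fixes one reading and exposes it: "peaks of
probability" are implemented as elementwise strict thresholding (the
binary-map description), not local-maximum detection; training-window
endpoints are inclusive (250-500 ms at 10-ms bins gives 26 decoders);
null permutations retrain on the full training set, mirroring the non-CV
cross-task training; smoothing is 1-D along TNT time and precedes the
AUC-matrix computation; argmax ties select the earliest attention
timepoint; voltage epochs are not baseline-corrected before decoding
(`baseline_correct` exists but is off by default); item states use the
any-future-block reading (an intrusive item is "regulated" only if it never
intrudes again); and a trial's decoded label for the decoded slope is taken
per timepoint from the thresholded map.

## The synthetic-data generator

The generator (`simulate_cohort` and friends) emulates the statistical
structure the analysis assumes, with known ground truth, so every stage can
be validated end to end.

* **Attention task**: the central image appears at 0 ms, the background
  image at 200 ms, and intrusion trials carry a Gaussian-windowed sinusoid
  (envelope FWHM 200 ms, 5 Hz theta carrier, occipital weight map) centred
  110 ms after the background image (310 ms absolute) — the latency, band
  and topography of the reflexive-capture signature the method relies on.
  Exploration trials carry a distinct component (160 ms, 10 Hz,
  right-parietal) so the attentional and perceptual models are separable.
* **Noise**: AR(1) per channel (coefficient 0.9, marginal sd 5 uV) plus a
  shared 10 Hz alpha oscillation with random phase per trial, weighted
  toward occipital sensors. This gives realistic autocorrelation and a
  spatially structured nuisance oscillation; full 1/f synthesis and
  forward-modeled scalp physics are deliberately out of scope, so passing
  tests demonstrate correctness of the *pipeline*, not performance on real
  recordings.
* **TNT task**: 24 No-Think items x 8 blocks per participant (epochs
  -200-3000 ms). Reported-intrusive trials receive one planted event —
  the attention intrusion component scaled by `event_amplitude` — at a
  latency uniform in (400, 800) ms, centred on the ~600 ms
  intrusive-reactivation peak; the default single 200-ms event per trial
  is stipulated, since no empirical per-trial event count is available.
  Reports are *sampled* from the true blockwise intrusion probabilities,
  not thresholded from the EEG, so behavioral and neural ground truth can
  be decoupled (e.g. zero-amplitude events for null tests).
* **Regulation structure**: the true intrusion probability declines
  linearly from 0.8 with a per-participant slope ~ N(-0.1, 0.05) per
  block, plus block-level jitter (sd 0.15) that is itself part of the
  recorded truth. The jitter serves two purposes: block-to-block
  fluctuation is a real feature of intrusion data, and it keeps the
  item-sampling (binomial) noise — sd about 0.09 with 24 items — small
  relative to the true blockwise variation, so the Pearson-r slope is
  recoverable: the expected attenuation of a recovered slope is roughly
  `sqrt((S^2 + J^2) / (S^2 + J^2 + B^2))` with S the linear signal sd, J
  the jitter sd and B the binomial sd, about 4% at these values. True SIF
  is `penalty + sif_sd * (rho * z(slope) + sqrt(1 - rho^2) * e)` with
  penalty 0.10, sif_sd 0.15 and rho the configured slope-SIF coupling
  (-0.5 by default); No-Think recall is Bernoulli at
  `baseline_rate - SIF`, so the expected recovered coupling after both
  attenuations is about -0.38 at n = 200.
* **Determinism**: every randomized stage draws from a named child seed
  (`child_seed`) derived from one global seed; a fixed seed reproduces
  bit-identical epochs, truth tables and decoding outputs.

## Numerical choices

* FIR band-pass: Hamming windowed-sinc designed by `signal::fir1`, applied
  as one centred convolution (zero-phase by kernel symmetry) with reflect
  padding; the order targets a transition band of half the low cutoff
  (minimum 2 Hz) and is capped by the epoch length.
* Morlet transform: unit-energy complex wavelets, `n_cycles = max(f/2, 3)`,
  FFT convolution; power is expressed as percent change from the -500-0 ms
  baseline computed on the decimated (50 Hz) output grid, so corrected data
  average to exactly zero over the baseline window; non-positive baseline
  power raises an explicit error.
* Smoothing kernel: Gaussian with sigma = FWHM / (2 sqrt(2 ln 2)),
  truncated at 4 sigma, normalized to unit sum (strength is a local event
  density in [0, 1]); reflect padding avoids deflating strength at the cue
  onset and offset.
* Time bins are averages of non-overlapping sample groups; bin centres are
  reported, and windows select bin centres inclusively at both endpoints.
* Forest seeds are derived per (timepoint, fold/permutation) from the
  global seed, so results do not depend on evaluation order.
* Mixed-model timepoints that fail to converge fall back to a
  participant-aggregated paired t and are logged; permutations on which
  the t-map function fails are dropped and counted, with a hard error
  above 10% drops.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` exercise the full pipeline at
reduced, fixed sizes chosen to keep a complete run small while leaving
every stage nontrivial: 12-channel montages, 24 attention trials per
condition, 8-participant cohorts with 12 No-Think items, 40-ms bins,
50-permutation nulls estimated from 8-trial subsets, and planted components
of 12 uV against 5 uV noise (the "high-SNR" regime used for recovery
checks; calibration checks run with zero-amplitude events and
block-stationary reports). Behavioral recovery checks use the full 24-item,
8-block design with 24- or 200-participant cohorts. The full-scale defaults
(200 null permutations over all trials, 20000-permutation cluster tests,
102-channel montages) remain the function defaults.

## Known limitations

* Synthetic EEG is stationary AR(1) + alpha; no 1/f spectrum, artifacts,
  channel interpolation or volume conduction. Preprocessing beyond
  filtering/binning/baseline (artifact rejection, ICA, re-referencing) is
  out of scope.
* Real-data headline values (e.g. a 0.69 attention-task peak AUC) are not
  reproducible from synthetic data and are not targets of the shipped
  checks.
* The LME state contrast refits the mixed model at every timepoint and
  permutation; at full scale (1000 permutations) it is by far the most
  expensive stage.
* The perceptual-vs-attentional model comparison shares all machinery with
  the attentional route; only the training pair differs.
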