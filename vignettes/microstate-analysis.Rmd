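---
title: "EEG microstate analysis: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind the package, the
parameters that matter and their defaults, the numerical choices made
where the standard analysis leaves room, and what the synthetic-data
validation does and does not establish.

## The microstate model

Spontaneous scalp EEG, viewed as a sequence of instantaneous potential
topographies, spends most of its time in a handful of quasi-stable
configurations that switch abruptly every 60–120 ms. The analysis treats
the *shape* of the field as the object of interest and its polarity as
irrelevant: in eyes-closed rest the dominant alpha generator reverses
sign every half cycle while the configuration persists, so every
similarity computation in the package uses the absolute (or squared)
spatial Pearson correlation across electrodes.

A subject's recording is reduced to topographies at peaks of the global
field power (GFP), the spatial standard deviation over channels,
computed in its population form (sum of squares divided by the channel
count). GFP peaks are moments of maximal field strength and
signal-to-noise; peak picking is strict (both neighbours smaller) and
confined to contiguous segments so that a splice between two
eyes-closed spans can never manufacture a peak.

## Clustering

The modified K-means treats maps as lines through the origin rather than
points: assignment maximizes squared spatial correlation, and the update
step returns the first principal eigenvector of the GFP²-weighted sum of
outer products of the members — the closed-form maximizer of the
cluster's explained variance when polarity is quotiented out. The
objective reported and monitored is the global explained variance (GEV),
the GFP²-weighted mean of the squared correlations between each peak map
and its assigned cluster map.

Weighting the eigenvector update by GFP² is deliberate: it makes the
update the exact argmax of the GEV for a fixed assignment, so each full
iteration is non-decreasing in GEV (asserted in code via the stored
trace) and the fit on ≤ 8 peaks provably reaches the same optimum as
exhaustive enumeration of assignments, which the tests check. Unweighted
updates — equivalent when clustering pre-normalized maps of equal GFP —
would break that monotonicity guarantee without changing results
noticeably.

Defaults: 10 random restarts, 100 iterations cap, convergence when the
GEV improves by less than 1e-6. Ties in assignment go to the lowest
cluster index; an emptied cluster is reseeded with the peak worst
explained by the current maps; the sign of a fitted map is fixed by
making its largest-magnitude channel positive. All randomness descends
from one integer seed through a splittable mixing function, so fits are
bit-reproducible.

The number of maps is selected by the mean silhouette over peaks under
the polarity-invariant distance d(x, y) = 1 − |corr(x, y)|; Euclidean
distance would treat a map and its negation as distant and is therefore
wrong for this data. Because the pairwise distance matrix is quadratic in
the peak count, the silhouette is evaluated on a deterministic subsample
of at most 2000 peaks (the fits themselves always use all peaks). On
synthetic cohorts with four generating maps the criterion selects K = 4
across the 2–7 range, matching the standard choice for this kind of
recording.

Group-level maps are built in two levels — per-subject clustering of peak
maps, then clustering of the pooled subject maps with equal weights
(the first level has already absorbed the GFP weighting) — and only from
the control group, so that the reference topographies are independent of
any clinical group. Fitted maps are labelled A–D by optimal one-to-one
matching (Hungarian algorithm on total |spatial correlation|, verified
against brute-force enumeration of all permutations) to deterministic
canonical templates: diagonal axes for A and B, an anterior–posterior
gradient for C, a fronto-central peak for D.

## Backfitting, smoothing, statistics

Backfitting labels every sample (not only peaks) with the
best-|correlation| reference map. Zero-variance samples — flat
topographies that occur only in degenerate or noise-free data — inherit
the previous sample's label, or the first subsequent valid label at a
segment start.

Temporal smoothing uses a sliding majority vote over a centered full
window of round(82 ms × rate) samples (21 at 256 Hz), iterated to a
fixed point with at most 10 passes, ties keeping the incumbent label.
The majority vote was chosen over the classical penalty-based relaxation
because it is deterministic, testable sample by sample, and has the one
property the analysis needs: a brief interruption (shorter than about
half a window) between two longer runs of one class is removed, so
inter-peak troughs of low GFP do not fragment microstate segments.
Smoothing never crosses segment boundaries, conserves the sample count,
and cannot invent a class absent from the window.

Per-subject statistics enumerate maximal same-label runs within
segments: occurrence is runs per second of analyzed time, coverage the
percentage of samples, mean duration the average run length in
milliseconds. Two identities hold exactly by construction and are
asserted over thousands of random sequences: coverages sum to 100%, and
occurrence × mean duration (s) equals the coverage fraction for every
class with at least one run. A class with no runs has occurrence 0,
coverage 0 and a *missing* mean duration (never zero), and missingness
propagates to the C/D ratios, which are only defined when the class-D
denominator is positive. Runs touching a segment edge are counted and
included in mean duration; they are truncated observations, so mean
durations carry a small downward edge bias that is identical across
groups and therefore cancels from comparisons.

## Group inference

Each clinical group is compared with the controls using Bayesian
estimation with a robust two-group model: each group's values are
t-distributed with its own mean and scale and a shared normality
parameter ν, with the reference broad data-scaled priors (normal on each
mean centered at the pooled mean with SD 1000× the pooled SD, uniform on
each scale over pooled SD × [1/1000, 1000], exponential with mean 29 on
ν − 1). Sampling is MCMC through JAGS: 4 chains × 2500 post-warm-up
draws by default, with split-R̂ on the effect size gating convergence at
1.01 (a warning, never a silent return) and effective sample size
reported. The standardized effect size d = (μ₁ − μ₂)/√((σ₁² + σ₂²)/2) is
summarized by its posterior mean, a 90% highest density interval
(shortest sorted-window interval), and the posterior probability of
falling outside the region of practical equivalence (−0.1, 0.1);
"significant" means that probability reaches 0.95. ROPE bounds, the
threshold and the HDI mass are configuration fields, not constants.

The comparison grid runs one such fit per clinical group × measure
(class C, class D, the C/D ratio) × parameter (occurrence, coverage,
mean duration), disease group first, so negative d means a reduction
relative to controls. No multiple-testing correction is applied across
the grid — the analysis design reports each cell's posterior on its own
terms; a correction would have to act on the posterior probabilities and
is left as an explicit extension point rather than a default.

The frequentist companion is a type-II ANOVA of each parameter across
clinical groups adjusted for age and sex (constant covariates are
dropped automatically; rank deficiency warns), with a median-centered
Levene test for homoscedasticity and per-group Shapiro–Wilk normality
checks — Shapiro–Wilk because it is the standard small-sample choice
where no specific test is mandated.

## The synthetic cohort as a validation instrument

The generator produces exactly the structure the analysis assumes: a
semi-Markov class sequence (gamma sojourns with shape 2 — mean equal to
the target duration, realistic dispersion, and none of the pile-up of
near-zero sojourns an exponential would give), one fixed topography per
class, a 10 Hz carrier with a slowly varying log-Ornstein–Uhlenbeck
envelope (τ = 0.5 s) to reproduce eyes-closed alpha dominance, a random
polarity flip per sojourn to exercise polarity invariance, and additive
spatially-independent 1/f noise scaled to a target state-signal to noise
RMS ratio. Reference conditions: four classes at 100 ms mean duration
with equal occurrence weights, 60 s records at 256 Hz, SNR 4, 19
channels; a disease-like group is encoded as a multiplicative
perturbation of class parameters. For the end-to-end detection
experiment the class-D duration factor is 0.92: with no between-subject
heterogeneity in the generator, the observable between-subject spread is
sampling plus measurement noise, and an 8% sojourn shortening is the
dose at which the full pipeline measures a class-D mean-duration effect
near d ≈ −0.8 to −1.2 at 25 subjects per arm, the magnitude regime of
interest for this analysis.

What passing these tests shows: the chain of estimators is correct and
polarity/scale invariant, maps and temporal parameters are recoverable
at realistic SNR, the Bayesian decision rule is calibrated under the
null (false-alarm fraction ≲ 5% over 100 null cohorts), and an injected
class-D deficit is detected with the correct sign while class C stays
quiet in the large majority of repetitions. What it does not show:
robustness to real artifacts (blinks, muscle, electrode pops), to
volume-conduction structure in the noise, to non-alpha vigilance states,
or to between-subject topographic variability — the generator has none
of these by design.

## Known limitations and numerical caveats

* **Compositional leakage.** Coverage sums to 100% by definition, and
  majority smoothing re-absorbs a disease group's surplus of short
  class-D runs into neighbouring runs. A pure class-D perturbation
  therefore shifts measured class-C statistics by a small systematic
  amount (standardized effect around +0.2–0.3 under the reference
  conditions). This is a property of the measurement definitions shared
  with the field's standard pipelines, not of the implementation; it
  occasionally pushes a class-C cell over the decision threshold.
* **Smoothing inflates durations.** Re-absorbing short runs raises mean
  durations relative to the generating sojourn means (tens of percent at
  82 ms / 100 ms sojourns). Comparisons are unaffected because the bias
  is common to all groups; absolute durations should be read as
  post-smoothing quantities, as is standard.
* **Effect-size recovery has a statistical floor.** The sampling SD of a
  two-group standardized effect at 25–30 subjects per arm is ≈ 0.27–0.30,
  so *any* estimator — including the sample Cohen's d — lands within
  ±0.35 of the true value in only ≈ 76–80% of repetitions; the
  posterior mean cannot beat that floor systematically, and the
  recovery-rate check in the acceptance suite reflects it.
* **EDF support is minimal by design**: 16-bit EDF/EDF+ with 1 s records
  and a single annotation channel — sufficient for routine resting EEG,
  not a general-purpose EDF library. Bad channels come from an optional
  BIDS-style `channels.tsv`, since EDF itself does not carry them.
* **Interpolation** of the single tolerated bad channel uses inverse
  squared great-circle distance weighting over all good channels rather
  than spherical splines; for one QC-grade channel on a 19-electrode
  montage the difference is negligible, and the exclusion rule (more
  than one bad channel) does the real work.
* The 2 s / 50% overlap Hann–Welch PSD and the conventional band edges
  (0.5–4, 4–8, 8–13, 13–30 Hz) define the alpha-dominance screen; only
  the 8–13 Hz alpha band is intrinsic to the analysis, the others are
  conventions.
* Test problem sizes (10 × 60 s cohorts for recovery, 25 per arm for
  detection, reduced MCMC draws in repetition loops) were chosen as the
  smallest sizes at which the checked properties are stable; they are
  the package's reference validation conditions, not statements about
  clinical power.
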