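---
title: "Methods: emotional-stress classification from EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotional-stress classification from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstress)
```

This vignette documents the model behind the package, the choices left
open by the protocol it implements, and what the synthetic-data tests do
and do not demonstrate.

## Problem and pipeline

The package classifies short EEG windows as *calm* or *stress*. Input is a
cohort of trials — one multichannel recording per participant per
stimulus, each rated by the participant on 1–9 arousal (calm → excited)
and valence (unpleasant → pleasant) scales — in the standard preprocessed
geometry of the public affect corpora: 32 channels, 8064 samples at
128 Hz, bandpassed 4–45 Hz. Four stages run in order: annotation,
segmentation + feature extraction, feature selection, k-NN classification
under cross-validation.

### Annotation

A trial is calm when `arousal < 4` and `4 < valence < 6`, stress when
`arousal > 5` and `valence < 3`. The two regions are disjoint by
construction (`arousal < 4` vs `> 5`). All inequalities are strict:
ratings exactly on a threshold stay unlabeled. On a continuous rating
scale boundary values have measure zero, but users relabeling integer-rated
corpora should be aware a rating of exactly 4 or 5 never labels. A
participant contributes only if both classes occur at least once;
`select_participants()` logs the exclusions.

### Segmentation

Each labeled 8064-sample trial is cut into 16 contiguous windows of
`floor(8064/16) = 504` samples (~4 s), each inheriting the trial label —
one rating was collected per trial, so no per-window relabeling is
attempted. Non-divisible lengths drop the tail remainder with a warning
rather than erroring: geometry stays predictable and no window mixes
rates. Windowing multiplies the training set 16-fold, which a k-NN
classifier needs, at the price of statistically dependent windows within a
trial; see *Leakage* below.

## The feature bank

Per 504-sample window, five families (673 columns at 32 channels, named
`family/channel/component`):

* **Statistical** (6/channel): mean; standard deviation with population
  (1/N) normalization; mean absolute first difference (1/(N−1)); mean
  absolute second difference `|x(n+2) − x(n)|` (1/(N−2)); both differences
  also divided by the standard deviation. A constant window has σ = 0 and
  the normalized differences are defined as 0 so the bank stays finite.
* **Band power** (7/channel): Welch PSD summed over seven contiguous
  bands 4–7.2, 7.2–10.4, 10.4–13.8, 13.8–17, 17–20, 20–23, 23–60 Hz.
  Band edges are half-open `[low, high)` so the touching bands partition
  the axis without double counting. The last band nominally extends to
  60 Hz although 4–45 Hz data carries no content above 45 Hz; it is
  summed as specified and simply captures the 23–45 Hz mass. Welch
  parameters are not fixed by the protocol; the defaults — 128-sample
  (1 s) window, 50% overlap, periodic Hann taper, per-window demeaning —
  are standard EEG practice and give seven averaged periodograms per
  504-sample window. All are configurable via `welch_config()`.
* **Higher-order crossings** (5/channel): the window is demeaned once,
  then `D_k` counts sign changes of the (k−1)-times backward-differenced
  series, k = 1…5. Differencing is a high-pass cascade, so the sequence
  is a cheap spectral summary. Exact zeros inherit the previous nonzero
  sign; an identically zero series counts 0. This follows the
  higher-order-crossings literature's standard construction.
* **Hjorth parameters** (3/channel): activity σ₁ (variance), mobility
  √(σ₂/σ₁), complexity √(σ₃/σ₂)/√(σ₂/σ₁), from the variances of the
  signal and its first and second differences. The window is demeaned
  before σ₁ — the raw mean square equals the variance only then, and on
  4–45 Hz bandpassed data demeaning is numerically inconsequential.
  Conventions: a constant window gives (0, 0, 0); σ₂ = 0 with σ₁ > 0
  gives complexity 0.
* **Frontal alpha asymmetry** (1): `|ln R| − |ln L|` with R and L the
  alpha-band power of right (Fp2) and left (Fp1) prefrontal channels.
  The alpha band defaults to the classic 8–13 Hz — the seven analysis
  bands straddle alpha, and no single one of them is canonical for the
  asymmetry index — and is configurable. A zero-power channel is a
  degenerate-input error (its logarithm is undefined), which cannot occur
  for nonzero recordings.

## Feature selection

### Separability fitness

For a feature subset S, the rating is
`inter_class_separability / intra_class_closeness` on the columns of S:
the mean Euclidean distance over all cross-class pairs (normalized by
`M_i·M_j` for class sizes `M_i`, a generalization needed because real
cohorts are imbalanced; the equal-size case reduces to the usual `M²`
normalizer), divided by the mean within-class pairwise distance with
self-pairs included (`M_i²` pairs per class). Collapsed classes (zero
within-class spread) get the sentinel rating 1e12 so perfect separation
ranks highest instead of aborting the search. The rating is invariant to
global positive scaling and rigid translation, and is computed from one
C-level pairwise-distance pass per evaluation.

Euclidean distance is scale-sensitive and the families differ by orders
of magnitude (µV means vs integer crossing counts), so features are
z-scored — with training-fold statistics — before any distance is taken.
The original protocol is silent on standardization; without it the rating
is dominated by whichever family has the largest units, which we consider
a defect rather than a behaviour to copy.

### Genetic algorithm

Chromosomes are binary inclusion masks. Defaults (`ga_config()`):
population 50, 100 generations, tournament selection (size 3), uniform
crossover at rate 0.9, per-bit mutation 1/n_features, elitism 1,
generational replacement — robust textbook settings chosen because the
protocol names the operators but no values. Offspring that lose every bit
are repaired by setting one uniformly random bit. Elitism makes the
best-so-far fitness non-decreasing, which every run asserts via its
returned history. All randomness flows from `random_seed`; identical seed
and inputs give bit-identical masks (the global RNG state is saved and
restored).

### PCA baseline

`stats::prcomp` on the (already z-scored) training fold, retaining the
smallest component count reaching 95% cumulative explained variance — a
common default where the protocol states none — or a fixed count.
Test-fold rows are projected with the training center and rotation.

## Classification and validation

k-NN with Euclidean distance; k defaults to 5 (the protocol fixes only
the *fold* k; an odd neighbour count avoids binary vote ties).
Residual ties (even k, or equal votes) break deterministically: larger
summed inverse distance among each label's voting neighbours first, label
order second.

Validation is stratified 3-fold: within each class, rows are shuffled by
an explicit seed and dealt round-robin, so per-fold class counts differ by
at most one. Per fold, standardization statistics, the GA fitness, and
the PCA rotation are all computed on the training rows only — selection
runs *inside* the folds. Running it once on all data would leak test
labels into the mask and inflate accuracy; published pipelines often
leave this unspecified, and the leak-free variant is the defensible one.

**Leakage across windows.** Windows of one trial share slow
non-stationarities in real EEG and may land in different folds, so
trial-level information can still leak. The synthetic generator is
stationary within trials (see below), which removes this channel in our
tests; for real data, trial-grouped splitting is the appropriate
extension and segment-level accuracies should be read as optimistic.

## The synthetic cohort generator

`generate_cohort()` emulates the target geometry so every stage is
testable without the EULA-gated corpus. Per channel, a trial is the sum
of three narrowband stochastic oscillators — flat-spectrum random-phase
noise confined to theta 4–8, alpha 8–13, beta 13–30 Hz, with RMS
amplitudes 4, 6, 3 µV (alpha-dominant resting activity) — plus
band-limited 1/√f-amplitude background noise (SD 4 µV) in 4–45 Hz.
Spectral synthesis keeps >95% of power inside 4–45 Hz, mirroring the
corpus bandpass. Stress trials multiply beta power by `1 + effect_size`
and divide alpha power by the same factor on the planted channels, and
scale Fp2 alpha power by `exp(asymmetry_shift)`. Ratings are drawn
uniformly strictly inside the calm or stress annotation region, so
annotation recovers the generated labels exactly and both classes are
guaranteed per participant.

Early in development the oscillators were fixed-frequency sinusoids per
trial; that gave every trial a stable spectral fingerprint which k-NN
used to identify trial membership, driving accuracy far above chance even
with no planted effect. Stationary random-phase narrowband noise removes
the fingerprint, and the no-effect control then sits at chance — a
property the generator must have for the planted-effect tests to mean
anything.

Defaults for effect sizes, where the emulated protocol offers no
analogue, were fixed once at `effect_size = 0.5` and
`asymmetry_shift = 0.5`: a band-power ratio of 1.5 between classes is a
moderate, plausible affect-related modulation that neither saturates the
classifier nor drowns in estimator noise.

**What passing tests show — and not.** The generator plants effects in
exactly the families the bank extracts, with known ground truth; recovery
and ordering results (GA ≥ PCA) demonstrate the *pipeline's mechanics* —
that selection finds genuinely informative columns and that validation is
leak-free — under favourable, stationary, artifact-free conditions. Real
EEG adds ocular/muscular artifacts, inter-channel correlation,
non-stationarity and label noise, none of which are modelled; synthetic
accuracies say nothing about accuracies attainable on real recordings.

## Problem sizes in tests and the acceptance script

Unit and acceptance runs use reduced cohorts chosen once: an 8-electrode
montage (Fp1, Fp2, F3, F4, C3, C4, O1, O2 — retaining the prefrontal pair
and the 4 planted channels), 1–3 participants, 8–12 trials, and the full
8064-sample trial length, since 504-sample windows (seven averaged
periodograms) are what give band-power estimates their intended
stability. These sizes keep the whole suite in the low minutes while
exercising every code path at study geometry; channel count scales the
feature bank linearly and affects no algorithmic decision. GA runs in
tests use population 24–30 × 30–60 generations, ample for the 169–255
column spaces they search.

## Known limitations

* Segment-level folds are optimistic for real data (see *Leakage*).
* The GA fitness is the separability rating, not wrapper accuracy; a
  mask optimal for the rating need not be optimal for k-NN.
* The band scheme treats 23–60 Hz as one block; on 4–45 Hz data its
  upper third is structurally empty.
* The asymmetry feature uses `|ln R| − |ln L|` as specified; for powers
  on opposite sides of 1 the absolute values make the index
  non-monotone in R/L, a property users comparing with the more common
  `ln R − ln L` index should note.
* No artifact handling: the pipeline assumes preprocessed, artifact-free
  input.
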