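---
title: "Microstate segmentation, transition complexity and classification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate segmentation, transition complexity and classification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EEGmicrostates)
```

# The model

Resting EEG topographies do not vary continuously: the average-referenced
scalp map stays quasi-stable for tens to hundreds of milliseconds and then
switches rapidly to another configuration. Microstate analysis models a
recording as a sequence of draws from a small dictionary of `k` unit-norm
topographies, each map defined only up to sign (the same generator
configuration produces both polarities as its sources oscillate). Everything
in this package follows from three modelling commitments:

1. **Polarity invariance.** All distances, assignments and statistics use
   the squared spatial correlation, never the signed one.
2. **GFP weighting.** The global field power (spatial standard deviation
   across channels) indexes how much topographic signal a sample carries;
   clustering uses topographies at GFP peaks and the fit criterion (GEV)
   weights samples by GFP.
3. **No Markov assumption for transition structure.** The central
   complexity measure `C` (LZ76 of the transition sequence) is sensitive to
   higher-order, non-stationary switching patterns that a first-order
   transition matrix cannot represent.

# Segmentation

`modifiedKMeans()` clusters observation topographies under
`d(u, v) = 1 − r(u, v)²`. The centroid of a cluster is the first principal
eigenvector of the summed outer products of its members — the maximizer of
summed `r²`, which is what makes the procedure the polarity-invariant
analogue of k-means. Initialization is k-means++ re-expressed in this
metric (seeding weights proportional to `1 − r²` to the nearest chosen
centre; this distance is already squared-correlation based, so no further
squaring is applied). Each fit iterates to a label fixpoint or until the
GEV changes by less than `1e-7`; 20 restarts are run and the best GEV wins.
Ties in assignment resolve to the lowest class index, so a fixed seed gives
bit-identical models. An emptied cluster is reseeded from the observation
worst fit by its current assignment.

Observations default to GFP-peak topographies (the classical choice: peaks
are the moments of maximal topographic signal-to-noise); clustering all
samples is a configuration switch (`clustering$gfpPeaks`). Backfitting
labels every sample by maximal `r²`. Temporal smoothing is off by default —
segment-length post-processing interacts with duration statistics, so it is
exposed (`minDurationMs`) rather than imposed; when enabled, sub-threshold
segments are iteratively absorbed into whichever neighbouring class
correlates better with their samples, shortest segment first.

## Choosing k

`selectKKL()` implements the Krzanowski–Lai criterion on the clustering's
own dispersion measure `W(k) = Σ (1 − r²(member, centroid))` — using the
same distance for fitting and model selection keeps the criterion
interpretable. `DIFF(k) = (k−1)^(2/p) W(k−1) − k^(2/p) W(k)` with `p` the
number of channels, and `KL(k) = |DIFF(k)| / |DIFF(k+1)|` peaks where the
dispersion curve elbows. Two boundary details matter:

- `W` is evaluated one `k` below the requested range (down to `k = 1`, the
  single principal map) so that the lowest tested `k` is selectable; with
  a range starting at 2 the criterion could otherwise never return 2.
- The highest tested `k` is never selectable (its `KL` needs `DIFF(k+1)`);
  the default range 2..8 therefore decides among 2..7.

On cohorts, the per-subject optima are summarized by their median, then all
subjects are refit at that common `k`, pooled per group, and reclustered
(`fitCohort()`) into cohort-level maps. `alignModels()` matches two models
by exhaustive permutation search on the summed `|r|` (exact for `k ≤ 8`,
greedy beyond) and returns the full correlation table, because automatic
alignment of microstate classes should always be inspected.

# Transition complexity

`C = microstateLZC(seq)` collapses each maximal constant-label run to one
symbol and counts LZ76 words. Conventions are pinned exactly, because
published LZ76 variants differ by ±1 word:

- exhaustive history with self-overlapping reproduction: the current word
  extends while it occurs as a substring of everything before its last
  symbol; it closes *including* the innovating symbol;
- the terminal word counts even if still reproducible;
- empty sequence → 0, single symbol → 1.

The suite fixes this convention against an independently written
brute-force parser, exhaustively over all binary strings up to length 12.

Run collapsing is the default because `C` is meant to measure
*transitioning*: without collapsing, the word count is dominated by dwell
lengths (and hence by sampling rate). Both the collapse and the optional
`log_k(n)/n` normalization (which maps uniform random sequences to ≈ 1)
are flags recorded in every output, and the classifier refuses to mix
features computed under different flags (config-hash check). Degenerate
case: a single-class sequence collapses to one symbol, `C = 1`, flagged.

The two classical comparison measures use the standard conventions from
the EEG complexity literature: Ω-complexity is `exp` of the entropy of the
normalized eigenvalue spectrum of the channel covariance (an effective
count of independent spatial components, 1 ≤ Ω ≤ channels), and
time-series LZC binarizes each channel at its median — scale-free by
construction — and normalizes the word count by `n / log2(n)`.

# Group statistics

- **Durations** are computed over maximal runs; runs touching an epoch
  boundary are censored (their true dwell is unknown) and excluded from
  duration means by default, while coverage always uses all samples.
- **ANOVA** (`value ~ group * class`) uses Type II sums of squares via
  `car::Anova`: with unbalanced diagnostic groups, Type II tests each main
  effect adjusted for the other without letting the interaction absorb
  main-effect variance. The all-values-equal degenerate design returns
  F = 0, p = 1 rather than 0/0.
- **Mann–Whitney U** converts to a z-score with a continuity correction
  applied toward the mean (clamped to z = 0 within ±0.5) and tie-corrected
  variance. This choice is validated exhaustively against the exact null
  distribution for group sizes 3..8: within 0.02 of the exact two-sided p
  throughout the decision-relevant tail (p ≤ 0.2) and within 0.04
  globally — the normal approximation is simply not accurate to 0.02 at
  mid-distribution U for tiny samples, so no implementation choice could
  do better there.
- **TANOVA** tests a topographic group difference per class. All subject
  maps are GFP-normalized and polarity-aligned to the *pooled* consensus
  (the principal topography of both groups combined), then the statistic
  `1 − |r(mean_A, mean_B)|` is permuted over group labels. Aligning to the
  pooled rather than each group's own consensus is deliberate: the pooled
  alignment is identical under every relabelling, whereas per-group
  alignment makes each permuted group collapse onto whichever topography
  dominates it, inflating permuted statistics and destroying power exactly
  when a real difference exists. With 999 permutations and the `(count +
  1)/(n + 1)` convention the attainable minimum p is exactly 0.001.

# Spectral feature and classifier

θRP is the Welch-estimated power in 4–8 Hz divided by power in 1–30 Hz
(2 s Hamming segments, 50% overlap, trapezoidal band integrals, mean over
channels). Band edges are configuration, not constants — clinical
definitions of "theta" vary — and relative powers over any partition of the
total band sum to 1 by construction.

The classifier is an SVM over standardized (θRP, C). The kernel default is
RBF with unit cost and a median-heuristic bandwidth (`1/(2·median²)` of
pairwise distances on the standardized training features): a smooth,
hyperparameter-free default appropriate for a 2-D feature space with a few
dozen subjects; a linear kernel is one flag away. Cross-validation is
stratified, the scaler and bandwidth are refit on each training fold only,
and out-of-fold predictions pool into a single confusion matrix. Reported
percentages round half-away-from-zero to one decimal (13/16 prints as
81.3, not the banker's-rounding 81.2). When a model must be applied to
clinical-format EEG, the supported path is to down-convert the training
recordings (`downsampleToClinical()`: channel subset, FFT resampling,
re-reference) and retrain, not to reuse the high-density model — enforced
by the feature-configuration hash.

# Preprocessing

Zero-phase band-pass (Butterworth design order 4, applied forward and
backward via `filtfilt`, i.e. an 8th-order magnitude response), common
average reference, optional resampling, and truncation to the first 20 s
(the standard resting-state analysis epoch; configurable). Verified
behaviour at 250 Hz: a 50 Hz line tone is attenuated to 0.64% RMS while
10 Hz passes at 99.99%. Resampling is FFT-domain (spectrum crop/pad):
numerically exact for band-limited signals, no group delay and no drift for
arbitrary rational ratios such as 512/1000; the identity resample is exact
to machine precision. Artifact rejection is out of scope — synthetic inputs
are artifact-free, and real-data cleaning pipelines are too site-specific
to hard-code.

# The synthetic generator

`generateEEG()` emulates the geometry of a resting eyes-open epoch:
`x(t) = a(t) · map[state(t)] + noise`, with

| parameter | default | rationale |
|---|---|---|
| channels | 64 | research-grade montage |
| fs | 250 Hz | analysis-grade rate; cheap and above any band of interest |
| duration | 20 s | standard resting epoch length |
| k (true maps) | 4 | the classical four resting classes |
| dwell | gamma, mean 60 ms, shape 2 | tens-to-hundreds of ms, right-skewed, non-geometric |
| carrier | 10 Hz, phase re-randomized per dwell | alpha-dominant resting EEG |
| SNR | 5 (RMS signal / RMS noise) | clearly recoverable but noticeably noisy |

The gamma (rather than geometric) dwell distribution makes the sample-level
sequence non-Markovian, so the complexity measure's core sensitivity is
exercisable; transition weights are arbitrary, allowing cyclic "repetitive
syntax" cohorts. What the generator does **not** emulate: 1/f background
spectra, spatially correlated sensor noise, volume-conduction structure
between maps, artifacts, or inter-subject map variability beyond noise.
Passing the recovery tests therefore demonstrates correctness of the
algorithms under known ground truth — not clinical performance, which can
only come from real cohorts.

A note on backfitted durations: at carrier zero-crossings the instantaneous
topography carries no signal and labels fragment, so unsmoothed backfitted
mean durations (≈ 33 ms at the defaults) sit below the generator's 60 ms
dwell; this is a property of any amplitude-modulated generator, is shared
by real alpha-dominated EEG, and is why duration comparisons must use a
common labelling configuration.

# Problem sizes and determinism

Simulation-based checks in the suite use 10 subjects × 20 s at 250 Hz with
64 channels for recovery/model-order properties, 200 repetitions at 199
permutations for TANOVA null calibration, and 20 repeated cohorts of
100/group for chance-level classification — sizes at which every asserted
property is stable across seeds while the whole suite runs in about a
minute. All stochastic stages (generator, restarts, folds, permutations)
take explicit seeds; identical seeds give bit-identical outputs, and every
serialized result embeds the hash of the configuration that produced it.

# Known limitations

- EDF support covers continuous, single-rate recordings (the clinical
  resting case); annotations and mixed-rate signals are not parsed.
- Class naming (A–D) against the shipped templates is a convenience for
  synthetic 10-20 montages; the templates are synthetic approximations of
  the canonical patterns and the alignment report should always be
  reviewed, as the naming is only as meaningful as the template match.
- The Mann–Whitney z approximation degrades below ~5 subjects per group
  (see above); exact tests are preferable there.
- `fitCohort()` assumes all subjects share one electrode montage; no
  interpolation across montages is provided.
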