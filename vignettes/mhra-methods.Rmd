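---
title: "Multilevel heterogeneous recurrence analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel heterogeneous recurrence analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices made where several were defensible, what the synthetic generators
do and do not emulate, and the known limitations.

## The model

Recurrence — a dynamical system revisiting the neighborhood of an earlier
state — is the organizing idea. Classical recurrence quantification treats
all recurrences alike; *heterogeneous* recurrence analysis first partitions
the state space into `K` subspaces and distinguishes recurrences by the
subspace (category) of the states involved. The multilevel extension
implemented here quantifies recurrence at three granularities within each
analysis window: the whole sequence (level 0), individual categories
(level 1), and two-step transition patterns (level 2). The machinery is
generic in the level, but the packaged feature set stops at level 2, where
the feature count `7·(1 + K + K²)` is still tractable (14,497 at
`K = 45`).

Three modelling assumptions are worth making explicit:

* **The window is quasi-stationary.** Each window (default 20 s) is treated
  as one sample of a dynamical regime; the HRQA vector summarizes the whole
  window. Regime changes inside a window are blurred.
* **Nearest-generator symbolization is meaningful.** States are labeled by
  their nearest Voronoi generator, so the geometry of the embedded state
  space must place dynamically similar states near one another. That is the
  job of the embedding step, and why embedding quality is scored before
  symbolization.
* **Transition structure carries the signal.** Classes are assumed to
  differ in *how* trajectories move between subspaces, not merely in
  amplitude. The surrogate generator enforces exactly this, which is what
  makes it a fair test bed.

### The chaos-game encoding

The categorical sequence `k_1, ..., k_L` is mapped to 2-D addresses by

\[ I_t = \alpha I_{t-1} + (\cos 2\pi k_t/K,\ \sin 2\pi k_t/K), \qquad
   I_0 = (0, 0), \]

with contraction factor \(\alpha = \tau \sin(\pi/K)/(1+\sin(\pi/K))\).
This choice of \(\alpha\) is what makes the encoding *decodable*: every
address lies within \(\alpha/(1-\alpha)\) of its current symbol's unit
anchor, anchors are \(2\sin(\pi/K)\) apart, and for \(\tau < 1\) the
resulting `K` first-level discs never overlap. Recursively, addresses
sharing their last `n` symbols lie within \(2\alpha^n/(1-\alpha)\) of each
other, so level-`n` transition patterns occupy disjoint sub-discs. The test
suite asserts both the contraction bound and the disc disjointness for
`K` in {2, 5, 45, 100}.

`ifs_project()` implements the recurrence as a first-order recursive filter
(`stats::filter`), which is exact and fast; the identity is also asserted
against a literal loop in the tests.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `window_s` | 20 s | window length; long enough for transition statistics, short enough for quasi-stationarity |
| `n_dims` | 4 | embedding dimension; for 62-lead EEG, 4 dimensions balance information retention (cross-entropy) and run time |
| `n_neighbors`, `min_dist`, `spread` | 5, 0.1, 1.0 | UMAP's locality settings, the reference configuration for multi-lead EEG |
| `K` | selected | number of Voronoi subspaces; chosen where the Davies–Bouldin curve over `K = 10..100` stabilizes (45 for the motivating EEG study) |
| `tau` | 0.99 | scaling control in (0,1); close to 1 keeps the fractal as spread out as disjointness allows |
| `B` | 10 | histogram bins for HENT/HGini; a modest count suited to windows of a few thousand samples. The bin count is not prescribed by the method definition, so it is exposed |
| `max_level` | 2 | highest transition level in the feature vector |
| GA `pool_size` | 200 (desk) | population per generation; `paper_scale = TRUE` restores 50,000 — a compute choice, not part of the method |
| `pm`, `slt` | 0.1, 20% of pool | swap-mutation probability and elite size |
| `stability` | 1.0 | fraction of LASSO runs a feature must survive; 1.0 encodes "consistently non-zero across all 30 runs" |
| `split`, `repeats` | 0.9, 30 | evaluation protocol: 90/10 random splits, repeated |

## Numerical and convention choices

These are the places where the method definition left genuine freedom; the
package makes each choice explicit, configurable, and documented here.

**Cross-entropy normalization.** The embedding-quality score compares the
norm profile of the embedded trajectory against that of the original
signal. Raw norm sequences are not probability distributions, so by default
both are rescaled to sum to one over the window before evaluating
\(-\sum_t p_t \log q_t\); this makes the score a proper cross-entropy
(bounded below by the entropy of `p`, with equality iff `p = q` — asserted
as a property test). A `raw = TRUE` escape hatch evaluates the literal
norm-based sum for users who only want the ranking.

**Voronoi generators.** How cell centers are obtained is not prescribed;
k-means centroids are used because a k-means partition *is* the Voronoi
tessellation of its centroids, the fit is reproducible given a seed, and it
composes naturally with the Davies–Bouldin selection sweep.

**Subspace-count stabilization.** The selection rule returns the smallest
`K` after which the per-step relative improvement of the index curve falls
below 1%. Two robustness details: the rule runs on the *running minimum* of
the curve, so a noisy uptick never masquerades as stabilization; and the
loess fit that mirrors the usual smoothed presentation of such curves is
applied only on grids of 25+ candidates — on short sweeps a local
polynomial blurs a sharp minimum and shifts the answer, which is visible on
generative mixtures with a known cluster count (the suite checks that five
separated Gaussian blobs yield `K* = 5` across ten seeds).

**Ties.** Nearest-generator ties break toward the lowest raw cell index;
equal GA fitness keeps the earlier-ranked arrangement. Both choices are for
determinism.

**HRR conventions.** The recurrence-rate definition admits three readings:
`C̄²/L²` (counting recurrent *pairs*, consistent with the recurrence-rate
tradition), `C̄/L²` (the formula as sometimes printed), and `C̄/L` (the
plain proportion of the window in the pattern). The package defaults to
the pair-counting `squared` convention and exposes `as_printed` and
`proportion`; every numeric check in the suite states its convention.

**Histogram conventions.** Bin edges span `(0, max d]` of each cluster's
own scaled distances, in `B` equal bins; the probability normalizer is the
number of unordered pairs, which is equivalent to doubling counts under an
ordered-pair normalizer and guarantees the probabilities sum to one. Exact
zero distances (identical addresses, i.e. identical symbol histories up to
the address resolution) are counted in the first bin rather than discarded
by the strict lower edge. A point-mass distance distribution therefore
gives `HENT = 0` and `HGini = 0` rather than undefined values.

**Degenerate clusters.** Downstream learners need finite features, so
empty clusters contribute zeros; singleton clusters contribute their HRR
with all distance-based metrics zero; zero variance sets HSkew/HKurtosis to
zero instead of NaN. No entries are silently dropped — the feature vector
always has its full combinatorial length.

**Moments.** HMean through HKurtosis use the number of distance pairs as
denominator (population moments over the pair multiset); this makes the
moment inequality `HKurtosis ≥ HSkew² + 1` hold exactly, which the suite
asserts, and matches the `C̄(C̄−1)/2` normalizer of the defining sums.

**Level-2 naming.** Internally a level-2 pattern stores (current,
previous); feature names read in transition order — `HVar_21_39` is the
transition *from* subspace 21 *to* subspace 39 — because that is how
transitions are discussed. The mapping is documented at `feature_vector()`.

**Box counting.** The grid is anchored at the point cloud's bounding-box
corner (determinism) and halves the bounding-square side ten times. The
regression range excludes trivially coarse scales (one box) and saturated
fine scales (more than one box per five points): both ends of the log–log
curve flatten — coarse boxes because everything fits in one box, fine boxes
because counts plateau at the number of points — and including either
biases the slope low. With this guard the estimator recovers dimension
2.00 for a filled square and 1.00 for a segment at 10,000 points. A
zero-extent cloud (all addresses identical) is assigned dimension 0, the
natural limit of a one-box covering at every scale. Indices are clamped
into the grid so boundary points cannot spill into a phantom box row.

**Genetic algorithm.** Crossover and mutation operators for permutations
are not prescribed, so the standard pair is used: order crossover (OX) and
swap mutation. Elitism (the top `slt` arrangements survive unchanged)
guarantees the best-fitness history is monotone non-decreasing, which the
suite asserts; it also makes the small-`K` exhaustive-optimum check
meaningful. Convergence stops the loop when the best fitness improves less
than `1e-4` over 10 consecutive generations. Fitness values are cached by
arrangement, which matters because elite arrangements recur every
generation. The fitness of an arrangement is evaluated on (at most) the
first few thousand pooled symbols — the box-counting dimension of the
address cloud stabilizes with a few thousand addresses, and this keeps the
search affordable.

**Anti-leakage protocol.** Within `mhra()`, the embedder, tessellation,
label arrangement, LASSO selection and models are all fit on the supplied
(training) recordings only and frozen into the returned object;
`predict()` applies the frozen maps. Group-aware splitting (windows of one
recording never straddle a train/test split) is the default in
`evaluate_repeated()`. The leakage property is tested by shuffling
recording labels before splitting, which drives the held-out AUC to chance.
One caveat discovered while building that check: with a few dozen
recordings, a *single* random labeling can be accidentally learnable (or
anti-learnable) at the recording level, so the per-shuffle null AUC is
widely dispersed (standard deviation around 0.2 here); the chance level is
therefore estimated by averaging the AUC over 20 independent label
permutations, with 80/20 group-aware splits so several test recordings
enter each evaluation. Splits are additionally stratified by class:
unstratified group draws make train and test class proportions
anti-correlate, which biases permutation nulls measurably below chance —
the well-known pessimism of grouped cross-validation on small samples.

**Embedding scope.** The embedder is fit once on pooled training samples
(global scope) rather than per recording; per-recording embeddings have
arbitrary orientation (e.g. PCA sign flips), which would make symbol
sequences incomparable across recordings under a shared tessellation.
Methods with an out-of-sample extension (PCA, UMAP via `uwot`'s transform)
are the ones a fitted model can use; Isomap, spectral embedding and t-SNE
are available for exploratory embedding of single recordings but cannot be
frozen into a predictive model. Locally linear embedding has no installed
implementation and is rejected with an informative error rather than
reimplemented.

## The synthetic generators

`simulate_attractor()` integrates the Lorenz
(σ = 10, ρ = 28, β = 8/3) and Rössler (a = b = 0.2, c = 5.7) systems with
fourth-order Runge–Kutta at `dt = 0.01`, discarding a 1000-step transient —
the standard recipe for these canonical regimes — and draws the "random"
system i.i.d. from a standard normal.

`generate_surrogate_eeg()` emulates the *shape* of a multi-lead EEG
dataset: 62 channels at 200 Hz by default, with each class's channels a
random (but seeded) linear mixture of its driving system's standardized
coordinates plus shared band-limited oscillations (6, 10, 20 Hz tones with
random phases) and independent Gaussian sensor noise at 10 dB SNR. Mixing
matrices and oscillation amplitudes are shared across classes deliberately:
classes differ *only* in their driving dynamics, so any discrimination the
pipeline achieves must come from recurrence structure, not amplitude or
spatial pattern. The mixing matrices play the role of a fixed electrode
montage: recordings generated in one call share it, and held-out evaluation
means holding out recordings within a dataset, not transferring across
montages.

What the surrogates do **not** emulate: volume conduction and realistic
forward models, 1/f spectra, artifacts (blinks, EMG), inter-subject
variability, or the subtlety of real emotional states. Passing the
discrimination test shows the pipeline recovers transition-dynamical class
differences end to end; it does not certify performance on real EEG.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen so the full suite completes
in minutes on one CPU while still exercising every stage at realistic
shapes: oracle comparisons use sequences of length ≤ 30 with `K ≤ 4`
(where brute force is exact and fast); geometry and GA checks use a few
hundred symbols; box-counting sanity uses 10,000 points; and the
end-to-end discrimination study uses 24 surrogate recordings of 62
channels at 200 Hz (80 s each, 96 twenty-second windows), `K = 8`
subspaces, PCA embedding to 4 dimensions, and a random-forest back end.
The study-scale settings (UMAP embedding, `K = 45`, GA pool of 50,000)
remain available through the same interfaces.

## Known limitations

* The GA is a heuristic; nothing guarantees a globally optimal label
  arrangement at large `K` (the search space at `K = 45` has ~1.2e56
  elements). The exhaustive-optimum property is only verifiable at small
  `K`.
* Box-counting dimension from a finite address cloud is a finite-scale
  regression, not the mathematical limit; its value depends (mildly) on the
  grid and fit-range policy, which is why those are fixed and deterministic.
* Feature vectors grow as `K²`; at `K = 45` most level-2 clusters in a
  4000-sample window are empty or singletons and carry fill values. That is
  by design (stability selection prunes them), but it means the effective
  feature dimension is far below 14,497.
* Embedding methods without an out-of-sample extension cannot back a
  predictive model; and UMAP, while reproducible given a seed, is sensitive
  to its locality hyperparameters.
* `evaluate_repeated()` operates on a precomputed feature matrix; its
  selection and tuning are leakage-free per repeat, but the unsupervised
  stages upstream (embedding, tessellation) are refit per training set only
  when the full `mhra()`/`predict()` protocol is used.
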