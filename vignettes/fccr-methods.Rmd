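---
title: "Feature-compressing channel ranking for motor-imagery EEG: models and methods"
author: "fccr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-compressing channel ranking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Motor-imagery brain-computer interfaces record EEG from tens to hundreds
of electrodes, but only a small subset — typically over the sensorimotor
cortex — carries class-discriminative signal. Selecting those channels
per subject improves classification, reduces hardware cost and shortens
setup time. This package implements a selection-and-classification
pipeline whose distinctive step is *feature compression*: per-channel
feature vectors are replaced by small-integer cluster signatures, turning
a trials × channels × features tensor into an ordinary trials × channels
matrix on which standard row-sparse feature-selection algorithms can rank
channels.

## Pipeline

Given `N` epoched trials `X_i` (M samples × C channels) with binary
labels:

1. **Preprocessing.** A linear-phase window-method FIR bandpass
   (default 0.1–40 Hz, order 33) is applied per channel, followed by an
   analysis-window cut (`[0.5, 3.0]` s and `[0.0, 4.0]` s are the
   benchmark choices at 100 Hz).
2. **Per-channel features.** Either `SP`: an order-16 autoregressive
   (Burg) spectrum, normalized to unit integral over `[0, fs/2]`, scaled
   by the signal variance and integrated over 11 bins centered
   0, 3, …, 30 Hz (15 in-bin evaluations each); or `TDP`: the log
   variance of the signal and of its first and second forward
   differences.
3. **Compression.** All training-trial feature vectors (every channel,
   trial and channel identity discarded) are pooled and clustered with
   k-means (Lloyd, k-means++ seeding, 10 restarts). Each (trial, channel)
   vector becomes the integer signature of its nearest centroid, giving
   the compressed matrix `X̃ ∈ {1..K}^{N̄×C}`.
4. **Channel ranking.** One of three row-sparse algorithms fits a weight
   matrix `W ∈ R^{C×L}` on `X̃` and the one-hot label indicator `Ỹ`;
   channels are ranked by `‖W(i,:)‖₂`:
   * **RFS** minimizes `‖X̃W − Ỹ‖₂,₁ + α‖W‖₂,₁` by iterative
     reweighting of the augmented system `A = [X̃ αI]`.
   * **RUFS** (unsupervised) jointly minimizes a robust clustering
     reconstruction `‖X̃ − GF‖₂,₁`, a graph-smoothness term
     `β tr(GᵀLG)` on a kNN heat-kernel Laplacian, a pseudo-label
     regression `γ‖X̃W − G‖₂,₁` and `η‖W‖₂,₁`, with `G, F, W ≥ 0` and
     `GᵀG = I`.
   * **SSLSR** greedily minimizes `‖X̃W − Ỹ‖²_F / N̄` under the
     row-support constraint `‖W‖₂,₀ ≤ C̄` by alternating forward
     selection (closed-form per-channel weight
     `θ = (Ỹ − X̃W)ᵀ X̃(:,i) / ‖X̃(:,i)‖²`) and conditional backward
     elimination (`Δ₊ < ν Δ₋`).
5. **Classification.** A regularized LDA (pooled covariance + ridge
   `1e-6·trace/dim`) is trained on the *original* feature vectors of the
   selected channels, concatenated; compressed signatures serve ranking
   only, so held-out trials never touch the cluster model.
6. **Evaluation.** Stratified 5×5 cross-validation; accuracy, precision,
   recall and F1 in percent; optionally an accuracy-versus-channel-count
   sweep.

```{r}
library(fccr)
ts <- generate_synthetic(synth_spec(seed = 1))
cv <- cross_validate(ts, fccr_config(ranker = "RFS", n_channels = 3, seed = 1))
cv
```

## Design choices in detail

Several points are under-determined by the verbal description of the
method; the package fixes them as follows.

**FIR design and application.** The "window method" is realized with a
Hamming window (the standard default with well-documented sidelobe
behaviour). The filter runs as a single causal pass; the linear-phase
group delay is compensated by shifting `floor(order/2)` samples with
edge replication, preserving both the trial length and the stated
order's magnitude response. A zero-phase forward-backward pass would
square the magnitude response and effectively double the order, so it is
not the default. Time-to-sample mapping is `index = round(t·fs)` with
half-open windows `[start, end)`, making sample counts unambiguous
(2.5 s at 100 Hz is exactly 250 samples).

**Spectral normalization.** "Spectrum multiplied by total signal power"
is read as: normalize the all-pole spectrum to unit integral over
`[0, fs/2]` (512-point trapezoid) and scale by the sample variance. Each
bin integrates the spectrum as the mean of 15 evaluations equally spaced
in `[center − 1.5, center + 1.5)` times the bin width; the 0 Hz bin
evaluates non-negative frequencies only and uses its effective (half)
width. The in-bin evaluation placement is one concrete reading of the
"evaluations per bin" convention; alternatives shift band powers by a
fraction of a bin width and do not change any ranking used here.

**Derivative operator.** `TDP` uses p-fold forward differences without
`fs` scaling: after the log, a sampling-rate factor is an additive
constant per feature, absorbed by LDA's location invariance.

**k-means internals.** The contract demands per-iteration WCSS traces,
k-means++ seeding with 10 fixed-seed restarts, deterministic
empty-cluster repair (the point farthest from its centroid is moved in)
and label canonicalization by ascending centroid norm (so signatures are
invariant to the solver's internal label permutation). The Lloyd loop is
therefore implemented in the package; the stock `stats::kmeans` is used
in the test suite as an independent quality cross-check.

**Signatures are ordinal codes: centering before ranking.** `X̃` feeds
regression-type rankers that carry no intercept. Signature values have
an arbitrary positive offset (labels 1..K), which would force noise
channels to act as intercept carriers and corrupt the ranking. The
pipeline therefore column-centers `X̃` (and `Ỹ` for the supervised
rankers) before ranking. Row-wise distances — hence the RUFS affinity
graph — and ranking equivariance are unaffected. The ranker functions
themselves are faithful to the printed update equations for whatever
input they are given. An optional one-hot signature mode was considered
and rejected as the default: it multiplies the column count by `K` and
the integer mode already recovers planted channels reliably.

**RFS numerics.** The reweighting diagonal `D_ii = 1/(2‖U(i,:)‖₂)` is
undefined at zero rows; a floor of `1e-8` on the row norm guards it.
The inner `N̄×N̄` solve falls back to a jitter of `1e-10·trace` if the
system is singular. Convergence is declared when the relative change of
the objective drops below `1e-6` (at most 100 iterations).

**RUFS numerics.** The cited inner solvers for the nonnegative blocks
are not specified; the package uses projected-gradient steps with
backtracking for `G` and `F` (each step accepted only if the objective
does not increase) and bound-constrained L-BFGS-B for `W ≥ 0` (the step
is discarded if it fails to improve). Orthogonality `GᵀG = I` is
enforced by a quadratic penalty (`ρ = 10³`) rather than manifold
retraction; the residual `‖GᵀG − I‖_F` is reported and stays below
`1e-2` on structured data. All `ℓ₂,₁` terms are smoothed as
`Σ_i sqrt(‖row_i‖² + δ²)` with `δ = 1e-8` so gradients exist at zero
rows; the recorded trace is the smoothed, penalized objective that is
actually minimized (monotone by construction), with the exact objective
also reported at convergence. The affinity graph uses 5 nearest
neighbours and a heat kernel at the median pairwise distance — the
default the unsupervised-learning literature assumes. The pseudo-class
count defaults to 2, the number of motor-imagery classes.

**SSLSR bookkeeping.** The printed stopping rule "until the selection
reaches the number of trials" is inconsistent with the row-support
constraint `‖W‖₂,₀ ≤ C̄`; the package stops at `C̄` selected channels
(a `stop_at_ntrials` flag restores the printed variant). `r` in the
row-support norm is taken as 2, matching the `‖W(i,:)‖₂` ranking rule.
Ties in forward and backward searches break toward the smaller channel
index. Zero-variance channels are excluded from the candidate set with
a warning.

**Hyperparameters.** `α = β = γ = η = 1` and `ν = 0.5` (none are stated
by the method's description; all are exposed in the config objects).
The cluster count is grid-searched over
2–8 (step 2), 10–90 (step 10), 100–700 (step 200) intersected with
feasibility (`K ≤ N̄` and at most the number of distinct pooled
vectors), by mean inner 5-fold training accuracy with ties toward the
smaller `K`. In practice the inner accuracy is flat over a wide range of
`K` (the method is insensitive to the cluster count), so the package's
default fixed value is `K = 10`, in the low-mid range of the grid:
large enough for signatures to resolve the band-power levels the
supervised regressions use, small enough that the trial-space
clustering inside the unsupervised ranker remains dominated by class
structure rather than within-class signature variability. The
desk-scale experiments below use it throughout.

**Cross-validation.** Folds are stratified per class with seeded
shuffling and are a pure function of `(N, labels, n_folds, n_repeats,
seed)`, so competing configurations sharing a seed see byte-identical
splits. Grid search for `K`, when enabled, runs nested inside each
training fold (leak-free); a per-subject variant (one grid search on all
trials) exists for protocol parity but is not the default. The "auto"
channel count is the argmax of the inner 5-fold accuracy curve with ties
toward fewer channels.

## The synthetic generator

Real benchmark recordings (118- and 59-channel motor-imagery sessions at
100 Hz) cannot be redistributed with a package, so validation runs on a
generator that emulates their statistical shape:

* per-channel AR(1) background (`ρ = 0.8`, unit marginal variance) —
  the 1/f-like broadband floor of EEG;
* one shared white source mixed into all channels (`gain 0.5`) —
  volume-conduction-style spatial correlation;
* on informative channels only, a mu-band (10–12 Hz) sinusoid whose
  amplitude depends on the class (defaults 2 vs 1, a 2:1 ratio), with
  phase drawn independently per trial and channel and amplitude
  modulated by a log-normal factor (`sd 0.2`) per trial and channel.

The phase randomization keeps the class signal in band *power* (as in
event-related desynchronization), not in time-locked waveforms. The
amplitude modulation reflects per-electrode gain and trial-varying
desynchronization depth; it is deliberately small relative to the class
effect (log-power sd 0.4 against a class log-power gap of `2 log 2 ≈
1.39`) but essential: without it the informative channels carry exactly
exchangeable power, and a greedy row-support selector will — correctly —
treat all but one of them as redundant, which no real electrode montage
exhibits. The default condition is desk-scale: 16 channels, 3
informative, 60 trials per class, 250 samples at 100 Hz.

What the generator does *not* emulate: realistic electrode geometry and
volume-conduction mixing matrices, artifacts (ocular, muscular), 1/f
spectral slopes beyond AR(1), non-stationarity across a session, and
class effects in coherence or phase. Passing the recovery experiments
therefore shows that the pipeline finds planted band-power structure
under correlated noise — not that it handles artifact-laden recordings.

## Validation experiments and problem sizes

The package's acceptance script and test suite recompute, at desk scale:

* closed-form feature identities (log-variance of white noise and of its
  first difference; the peak bin of a 10 Hz tone; the equality of the
  centroid and pairwise WCSS forms);
* monotone convergence of the RFS reweighting and agreement of its
  converged objective with an independent quasi-Newton minimization of
  the smoothed convex objective (20 instances, `N̄ ≤ 50`, `C ≤ 20`,
  relative gap `< 1e-3`);
* exact trajectory equality of the greedy forward-backward selection
  with a brute-force reimplementation (30 instances, `C ≤ 6`,
  `N̄ ≤ 12`);
* feasibility and monotonicity of the RUFS block descent (20 instances);
* informative-channel recovery and top-3-channel cross-validated
  accuracy on the default generator over 20 seeds (5-fold CV per seed;
  the full 5×5 protocol is exercised separately at a smaller problem
  size), plus chance-level behaviour on the equal-amplitude null
  generator.

These problem sizes are the package's own desk-scale choices; the
pipeline itself has no scale-dependent switches.

## Known limitations

* The RUFS inner solvers are substitutes with the same feasibility
  contract as the cited originals; absolute objective values are
  implementation-specific even though feasibility and monotonicity are
  guaranteed.
* The ranking treats signatures as ordinal integers; a one-hot mode
  exists conceptually but is not implemented as a config switch.
* EDF support is a minimal 16-bit reader/writer (one data record per
  trial, labels in a JSON sidecar); EDF+ annotations are not parsed.
* Precision/recall/F1 use class 1 as the positive class by default, with
  macro averages alongside; the choice is a convention, not derivable
  from the method.
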