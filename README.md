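# fccr — feature-compressing channel ranking for motor-imagery EEG

Multichannel motor-imagery EEG carries class-discriminative signal on a
small, subject-specific subset of electrodes. `fccr` implements a
channel-selection and classification pipeline for epoched EEG built
around two ideas:

1. **Feature compression.** Per-channel feature vectors — order-16
   autoregressive band spectral power (11 bins, 0–30 Hz in 3 Hz steps)
   or time-domain parameters `TDP(p) = log var(d^p x)`, `p = 0, 1, 2` —
   are pooled over all training trials and channels, clustered with
   k-means, and replaced by their integer cluster signature. The
   trials × channels × features tensor collapses to an ordinary matrix
   `X̃ ∈ {1..K}^{N̄×C}` (rows trials, columns channels).
2. **Convergent row-sparse channel ranking.** On `X̃` and the one-hot
   label indicator `Ỹ`, a weight matrix `W ∈ R^{C×L}` is fitted by one
   of three algorithms with convergence guarantees, and channels are
   ranked by `‖W(i,:)‖₂`:
   - **RFS** — `min_W ‖X̃W − Ỹ‖₂,₁ + α‖W‖₂,₁`, solved by iterative
     reweighting;
   - **RUFS** — robust unsupervised selection,
     `min ‖X̃ − GF‖₂,₁ + β tr(GᵀLG) + γ‖X̃W − G‖₂,₁ + η‖W‖₂,₁`
     with `G, F, W ≥ 0`, `GᵀG = I`, `L` a kNN graph Laplacian;
   - **SSLSR** — greedy forward-backward minimization of
     `‖X̃W − Ỹ‖²_F / N̄` under the row-support constraint
     `‖W‖₂,₀ ≤ C̄`.

Held-out trials are classified by regularized LDA on the *original*
features of the selected channels under a stratified 5×5
cross-validation; compressed signatures are used for ranking only. A
seeded synthetic generator plants mu-band (10–12 Hz) class-dependent
oscillatory power on a known channel subset over correlated AR(1) noise,
so every stage is testable without any external recordings.

## Worked example

```r
library(fccr)

# 16 channels, channels 1-3 carry a 2:1 mu-band amplitude class effect
ts  <- generate_synthetic(synth_spec(seed = 1))
fit <- fccr(ts, config = fccr_config(feature = "SP", K = 10,
                                     ranker = "RFS", n_channels = 3,
                                     seed = 1))
fit
#> <fccr> SP features, RFS ranking, K = 10 clusters
#>   selected 3/16 channels: ch1, ch2, ch3
#>   training accuracy: 100.0%

cv <- cross_validate(ts, fccr_config(ranker = "RFS", n_channels = 3, seed = 1))
cv
#> <fccr_cv> SP/RFS, 25 folds
#>   accuracy   95.00 +/- 5.77 %
#>   precision  92.82 +/- 8.20 %
#>   recall     98.33 +/- 3.40 %
#>   f1         95.34 +/- 5.26 %
```

The fitted model found exactly the three planted channels (1-3); the
25-fold mean accuracy of 95 % reflects the 2:1 amplitude ratio of the
default condition. `coef(fit)` returns the per-channel weights, `plot(fit)`
shows them next to the ranker's objective trace, and
`channel_sweep()` produces the accuracy-versus-channel-count curve.
A thin command-line front end over the same functions is installed at
`inst/cli/fccr.R` (subcommands `simulate`, `run`, `compare`).

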