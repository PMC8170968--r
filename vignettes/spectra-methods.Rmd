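---
title: "Methods: spatial-frequency-temporal decoding of motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-frequency-temporal decoding of motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectra)
```

## The decoding problem

Imagining a movement attenuates the sensorimotor mu/beta rhythms over the
corresponding cortical area (event-related desynchronization). A two-class
motor-imagery BCI must decide, from one cue-aligned EEG epoch, which of
two tasks was imagined. The discriminative information lives in the
*spatial covariance* of the band-filtered signal: different tasks
attenuate band power at different electrode subsets. This package decodes
that structure with a fixed, fully deterministic feature pipeline and an
SVM; the only data-driven hyperparameter is a temporal delay, chosen by
nested cross-validation.

## Pipeline

1. **Preprocessing.** Common average reference per trial, Butterworth
   band-pass 7–30 Hz (one wide band covering mu and beta), extraction of
   the 0.5–2.5 s post-cue window. The Butterworth order is not critical;
   we use order 4 applied forward–backward (`signal::filtfilt`), so the
   pass is zero-phase and epochs stay aligned to the cue at the cost of a
   doubled effective order. Both order and causality are configurable.
2. **Windowing.** The epoch is cut into `n = 3` windows delayed by τ
   samples. The windows share length `L = T − (n−1)τ` *inside* the stated
   epoch: we truncate rather than extend the epoch, so no data outside the
   analysis window is ever consumed; with the default 2 s epoch and τ ≤
   10% of `fs`, at most 20% of samples are traded for the temporal
   diversity of the windows.
3. **CSP.** Per window (and per stacked window pair, below) spatial
   filters come from the generalized eigenproblem on trace-normalized
   class-mean covariances. Six filters (3 pairs) per process.
4. **CSSP.** Each of the `n(n−1)/2` window pairs is stacked
   channel-wise (`2C × L`); CSP on the stack realises filters with a
   frequency response shaped by the delay — a spatio-spectral filter.
5. **Tangent-space mapping.** Each filtered trial's normalized covariance
   is projected to the tangent space at the Karcher mean of the *training*
   covariances of its process. With six filters that yields 21 features
   per process next to the 6 log-variance CSP features: 27 per process,
   162 fused.
6. **Selection and classification.** Fisher-score ranking, top `r = 10`,
   z-scoring with training statistics, RBF-SVM.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `band` | 7–30 Hz | analysis band (mu + beta) |
| `filter_order` | 4 | Butterworth order (zero-phase doubles it) |
| `epoch_window` | 0.5–2.5 s | cue-relative analysis window |
| `n_windows` | 3 | delayed windows; 1 reduces to the single-window tangent-space predictor |
| `tau_grid` | 1..round(0.1·fs) | candidate delays (samples); subject-dependent optimum |
| `m_pairs` | 3 | CSP filter pairs (6 filters, d = 6, 21 TSM features) |
| `r` | 10 | features kept after ranking |
| `svm_cost`, `svm_gamma` | 1, 1/r | SVM hyperparameters (below) |
| `cv_repeats × cv_folds` | 10 × 10 | outer evaluation |
| `inner_folds` | 10 | inner CV for τ |

The delay grid tops out at 10% of the sampling rate because larger delays
add computation without adding discrimination, and small delays are
preferable for real-time use — hence ties in the inner CV resolve to the
*smallest* candidate τ. τ is re-selected inside every outer training fold
(the stricter reading of "tuned on training data only"), not once per
subject.

## Numerical choices

- **Whitening rank guard.** Common average referencing removes one degree
  of freedom, and a zero-delay CSSP stack duplicates channels, so the
  composite covariance `C⁺+C⁻` can be exactly singular. Whitening is
  therefore restricted to the principal subspace (eigenvalues `> 1e-8 ×`
  the largest); filters never point into a null direction. A ridge of
  `1e-9·tr/d` is still added to near-singular *trial* covariances before
  the manifold operations. An error is raised when fewer directions
  survive than filters requested.
- **Karcher mean.** Fixed-point iteration with unit step, initialized at
  the arithmetic mean, tolerance `1e-8` on the gradient norm, at most 50
  iterations (typically ~10 suffice at d = 6); non-convergence warns and
  returns the best iterate with `converged = FALSE`. Matrix sqrt/log/exp
  use symmetric eigendecompositions with eigenvalue floor `1e-12`.
- **Vectorization order.** Tangent matrices are vectorized by the
  row-major upper triangle, diagonal first in each row, off-diagonals
  scaled by √2. The order is fixed so selected-feature indices are
  portable across fits; the scaling makes the Euclidean norm equal the
  affine-invariant distance.
- **Eigen tie-breaks and signs.** Filters are ordered by eigenvalue
  (stable sort); each eigenvector's first nonzero component is made
  positive, so refits are bit-reproducible.
- **Degenerate Fisher scores.** A feature with zero within-class variance
  in both classes but separated means is assigned `+Inf` and ranks first
  (it separates perfectly); identical columns score 0. Ties in ranking
  break by ascending column index.
- **SVM hyperparameters.** Cost 1 and γ = 1/r on standardized features —
  the `1/n_features` heuristic made explicit. Standardization uses
  training-fold statistics only; RBF kernels are scale-sensitive, so this
  is applied after selection, before the SVM.
- **κ banding.** The conventional agreement bands are printed with
  non-contiguous bounds; values are rounded to two decimals before
  banding, so 0.205 is "Poor" and 0.21 "Fair".
- **Folds.** Stratified by per-class round-robin after a seeded shuffle;
  repeat k of the outer CV uses seed `seed + k − 1`. All randomness in
  the package funnels through explicit seeds.

## The synthetic generator

`generate_trials()` draws a random orthonormal mixing matrix `A`, mixes
i.i.d. Gaussian noise through it (spatially correlated broadband
background), and adds narrowband oscillations (random frequency in
`signal_band`, random phase per trial) on fixed columns of `A`. Class ±1
scales the k-th source amplitude by `(1 ± δ)` with alternating sign per
source, so the classes differ in band-limited spatial covariance exactly
as ERD does. The depth δ solves `((1+δ)/(1−δ))² = 1 + snr`, making `snr`
the class band-power variance ratio minus one, and the base amplitude is
`√snr`, making it also the source-to-noise variance ratio; `snr = 0`
collapses both classes onto one distribution (the null case).
`generate_lag_trials()` instead gives both classes the *same* spatial
pattern and amplitude but different oscillation frequencies: plain CSP is
blind to this contrast, while a delay-embedded stack resolves it best at
delays where the two frequencies dephase most (`planted_tau()` computes
that delay), which is what the τ-recovery test exploits.

What the generator does *not* emulate: volume-conduction forward models,
ocular/muscular artifacts, non-stationarity across a session, 1/f
spectral shape (white noise is used; a pink-noise variant would only
rescale the band). Passing tests on this data therefore demonstrates the
*mechanics* of the pipeline — correct geometry, no leakage, sensible
selection — not performance on real recordings.

## Problem sizes

The shipped evaluation uses 200 trials/class × 10 channels at 100 Hz for
the end-to-end checks (error < 10% at `snr = 5`, 40–60% on null and
label-permuted data), and 30 trials/class × 8 channels over 10 seeds for
delay recovery on a 5-delay grid. These sizes give binomial confidence
bands narrow enough for the stated thresholds while keeping a full run in
minutes on one CPU core.

## Known limitations

- Two classes only; multi-class extensions (e.g. one-vs-one CSP) are out
  of scope.
- One wide 7–30 Hz band; no per-subject filter-bank learning.
- The Karcher mean assumes moderately conditioned covariances; extremely
  ill-conditioned inputs fall back on the eigenvalue floor and may lose
  precision.
- The archive format stores float64 only.
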