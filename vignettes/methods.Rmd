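---
title: "Hybrid convolutional-transformer heartbeat classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid convolutional-transformer heartbeat classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatformer)
```

## The problem

Heartbeat-level arrhythmia classification assigns each annotated beat of a
single-lead ECG to one of the five AAMI classes: **N** (normal and
bundle-branch-block beats), **S** (supraventricular ectopic), **V**
(ventricular ectopic), **F** (fusion) and **Q** (unclassifiable/paced/
artifact). Two properties make the task awkward for any single
architecture: the discriminative signal is partly *local morphology* (a
widened QRS, an early or absent P wave) and partly *context over the whole
window*, and the class distribution is severely imbalanced — normal beats
outnumber fusion beats by roughly two orders of magnitude in archival
recordings.

`beatformer` implements a hybrid model for this task: a 1-D convolutional
front end for morphology, a BERT-style bidirectional transformer encoder
for global context, a cross-modal attention + gated fusion stage that
merges the two feature streams, and a focal-loss training loop that
counteracts the imbalance. Every layer is written natively in R with
explicit forward and backward passes, so the package trains on a single
CPU with no external deep-learning runtime; the gradients of every layer
are verified against central finite differences in the test suite.

## Model

### Convolutional front end

Each beat is a fixed window of `window_len` samples (default 360 = 1 s at
360 Hz, centered on the annotated R peak). A stack of blocks applies

1. a *valid* (un-padded) 1-D convolution, `y_t = sum_k w_k x_{t-k+1} + b`;
2. a residual connection from the block input, center-cropped to the valid
   length, passed through a 1x1 convolution if and only if the channel
   counts differ;
3. ReLU;
4. non-overlapping max pooling (window 2), a trailing partial window being
   pooled as-is;
5. dropout (training only).

A fully connected map then reshapes the final feature map into a fixed
`T x d_c` feature sequence `C` for the encoder, independent of the window
length. Pooling is implemented as plain max pooling; a variant that wraps
the downsampling inside a bias and activation would be nonstandard and is
not offered.

### Transformer encoder

The encoder projects `C` into the model space with a kernel-3 "same"
convolutional embedding, prepends a learned `[CLS]` vector, and adds
*learned* positional embeddings (one trainable vector per position, not
sinusoids). `n_layers` pre-LayerNorm encoder layers follow, each

    x -> x + Dropout(MHA(LN(x)))  ->  u -> u + Dropout(FFN(LN(u)))

with multi-head scaled dot-product attention
`softmax(QK'/sqrt(d_k)) V` and a `d_model -> d_inner -> d_model` ReLU
feed-forward. Padding positions are masked by assigning their keys a
`-Inf` logit: a masked key receives exactly zero attention weight, which
gives the test-asserted invariance of the `[CLS]` summary to appended
padding. Pre-LayerNorm ordering (with a final LayerNorm) was chosen for
optimization stability at the small scales this package targets; the
alternative post-LN ordering is not exposed. After the stack, the `[CLS]`
output is the sequence summary and the remaining positions pass through a
trailing lightweight convolution — implemented as a depthwise kernel-3
"same" convolution, one filter per channel — to give the encoder-side
sequence `B`.

The default geometry is 4 layers x 4 heads with `d_k = d_v = 64` and
`d_model = 256`; a 768-dimensional, 12-head geometry is reachable through
the same configuration surface. Masked-segment pretraining is out of
scope: the model is trained supervised end-to-end.

### Cross-modal gated fusion

`C` (morphology stream) and `B` (context stream) are projected to a shared
dimension `d`:

    C' = C Wc + bc,   B' = B Wb + bb

Cross-modal attention aligns them, with queries from `C'` and keys/values
from `B'`:

    A = softmax((C' Wq)(B' Wk)' / sqrt(d_k)),   F_CB = A (B' Wv)

computed per head on `h` blocks of `d/h` columns (with `h = 1` this is the
literal single-matrix form). A sigmoid gate computed from the concatenated
streams blends them elementwise:

    g_t = sigmoid(Wg [C'_t ; F_CB,t] + bg),
    F_t = g_t * C'_t + (1 - g_t) * F_CB,t

so every fused element lies between its two sources by construction. The
classifier mean-pools `F` over valid time steps, concatenates the `[CLS]`
summary, and applies a linear softmax layer. Both encoders and the fusion
stage train jointly by default; a `two_stage` flag freezes the encoders
and trains only fusion + head, for the setting where the streams are
trained separately first.

### Loss and optimization

Class imbalance is handled by the focal loss

    FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t)

with `gamma = 2` by default and `alpha` defaulting to inverse class
frequency normalized to mean 1, so minority classes carry weights above 1.
(The weights are therefore *not* confined to (0,1]; any positive vector is
accepted.) `p_t = 0` is clamped to `1e-12` with a warning. Optimization is
Adam under the warm-up / inverse-square-root schedule

    lr(step) = lr_max * min(step / warmup_steps, sqrt(warmup_steps / step))

with the warm-up fraction defaulting to 0.08 of total steps (inside the
conventional 5–10% band). After each epoch the model is scored on the
validation split and the best weights by validation **macro-F1** are kept;
macro-F1 rather than accuracy, because with 84% majority class an
accuracy-selected model can ignore the minorities entirely. Early stopping
halts after `patience` (default 5) epochs without improvement. All
randomness — initialization, shuffling, dropout, augmentation — derives
from one seed, so a run is exactly reproducible.

Defaults that the underlying method leaves open (`lr_max = 1e-3`, batch
64, `max_epochs = 50`, `gamma = 2`) are engineering choices, exposed in
the configuration.

## Data path

For WFDB recordings, the package reads headers, format-212/16 signal files
and MIT-format annotations natively, takes the first lead (MLII in most
arrhythmia-archive records), band-pass filters the whole record at
0.5–50 Hz (Butterworth `signal::butter(4, ...)` applied forward-backward
with odd-reflection padding sized to the low corner's transient, so the
response is zero-phase and edge-clean), segments a centered half-open
window around each annotated R peak, maps symbols to AAMI classes
(`N,L,R,e,j -> N`; `A,a,J,S -> S`; `V,E -> V`; `F -> F`; `f,u -> Q`),
skips-and-counts boundary and unmappable annotations, and z-scores each
beat individually. Whether normalization should be per-record or per-beat
is genuinely open; per-beat is the default because it is robust to
inter-record gain differences, and the order filter → segment → normalize
is fixed. The stratified 70/10/20 split rounds per-class counts by largest
remainder, so every class count differs from its exact target by less
than 1. Training-split minority beats can be augmented by time-stretching
(uniform in [0.9, 1.1]) and amplitude scaling ([0.8, 1.2]).

## The synthetic generator

Because the archival recordings cannot be bundled, the package ships a
generator whose beats are sums of five Gaussian bumps (P, Q, R, S, T) on
the unit interval plus white noise and a shared per-beat timing jitter.
Class templates differ the way their clinical counterparts do, at cartoon
level:

| class | morphology |
|---|---|
| N | canonical P-QRS-T, R amplitude 1 |
| S | P-wave center shifted 0.08 earlier |
| V | R width tripled, P absent |
| F | parameter-wise average of N and V |
| Q | all amplitudes redrawn uniformly per beat |

Defaults are `noise_sd = 0.03`, `jitter_sd = 0.01`; the P amplitude (0.25)
was set so that the N/S distinction — which rests entirely on the P wave —
survives the highest noise level the generator contract promises to
support (`noise_sd = 0.05`), as verified by the nearest-centroid
separability test (>= 90% with class centroids from 50 beats each). The
`imbalanced_class_counts()` preset reproduces archive-like proportions
0.84/0.026/0.067/0.007/0.074 for N/S/V/F/Q via `round(total * p)`; the
proportions are applied as stated, so the realized total can exceed the
request by about 1.4%.

What the generator does **not** emulate: baseline wander and powerline
interference, inter-beat rhythm context, multi-lead morphology,
record-level patient effects, or the true within-class morphological
diversity of clinical recordings. Tests passing on synthetic beats
demonstrate that the architecture, gradients, and training loop work and
that the pipeline can learn class-discriminative morphology under heavy
imbalance — they are not evidence of clinical-grade accuracy on real ECGs.

## Numerical choices

- Attention masks use `-Inf` logits; a query whose keys are all masked is
  a degenerate-mask error.
- LayerNorm uses `eps = 1e-5`; z-scoring refuses signals with
  `sd < 1e-12` (degenerate-input error).
- Zero-denominator metrics (e.g. precision of a never-predicted class)
  return 0 with an explicit flag so macro means stay defined; aggregate
  averages are unweighted macro by default, support-weighted on request.
- Max-pool ties take the first index; weight init is Kaiming-uniform for
  conv/linear weights, zero biases, Gaussian(0, 0.02) positional/[CLS]
  embeddings.
- Focal-loss gradients flow through the softmax analytically; the whole
  model's backward pass is checked against finite differences at
  tolerance ~1e-6 in the test suite.

## Problem sizes used in the shipped experiments

The packaged experiments run a reduced geometry (conv channels 8→16,
`d_model = 32`, 2 layers, 2 heads, `T = 16`, `d_c = 32`) on ~2000
synthetic beats with the archive-like imbalance, 10 epochs — small enough
to train in minutes on one CPU while exercising every architectural
component, and large enough that held-out accuracy (≥ 0.9) and macro-F1
(≥ 0.75) are meaningful under the imbalance. A 32-beat memorization run
checks that the model can drive training accuracy to 100%, the standard
sanity check that gradients reach every stage. Full-size defaults
(channels 16/32/64, `d_model = 256`, 4x4) remain available through
`model_config()` for users with real recordings and more patience.

## Known limitations

- Per-sample (not batched) tensor operations: training scales linearly in
  beats and is practical up to a few thousand beats per epoch on one CPU.
- R-peak positions are taken from annotations; there is no detector.
- WFDB support covers header + signal formats 212/16 and MIT annotations —
  the subset used by the standard arrhythmia archives.
- The nine-class variant of the task is reachable by supplying a
  nine-label vocabulary and templates, but no canonical nine-class
  template set ships with the package.
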