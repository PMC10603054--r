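---
title: "Methods: dynamic protein-RNA binding prediction from sequence and in vivo structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic protein-RNA binding prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

RNA-binding proteins (RBPs) recognize their targets through a combination of
sequence elements and structural context: many RBPs prefer motifs presented
in single-stranded regions, and the same transcript can present different
structures in different cellular conditions. `bindnet` predicts whether a
101-nt RNA window is a binding site for a given RBP from two inputs:

1. the RNA **sequence**, tokenized into overlapping k-mers and embedded by a
   trainable multi-head self-attention encoder, and
2. the in vivo **icSHAPE reactivity** of each base, a per-base score in
   [0, 1] where high values indicate unpaired (single-stranded) bases,
   computed by this package from raw probing counts.

Because the structure input is experimental rather than predicted, a model
trained in one condition can be queried with another condition's reactivity
profile — the "dynamic" prediction setting is just `predict` with different
structure data; no special mode exists.

# icSHAPE reactivity scoring

Inputs are per-base RT-stop counts for two mock (DMSO) and two treated (NAI)
replicate libraries, plus per-base coverage ("base density", BD) for the
DMSO replicates. Per transcript, a window of `window_size` bases slides
5'→3' by `window_step`; within each window:

1. **Merge** replicates by direct addition.
2. **Normalize** each merged vector by the mean of its sorted values with
   ascending ranks in `(0.90 n, 0.95 n]`. Slice boundaries are rounded to
   the nearest integer; if rounding collapses the slice the single rank
   `ceiling(0.95 n)` is used, so the factor is always defined. A
   non-positive factor (e.g. an all-zero window) skips the window rather
   than erroring.
3. **Enrich**: `e = (rt_nai − α·rt_dmso) / bd_dmso` with background factor
   `α` (default 0.25). Bases with zero denominator are undefined.
4. **Rescale** to [0, 1] between the 5% and 95% quantiles of the defined
   enrichment values (linear-interpolation quantiles, computed per window),
   clamping outside values. Bases whose *raw merged* DMSO coverage is below
   `coverage_min = 200` are reported as NULL. The source text is internally
   inconsistent between "≥ 200" and "more than 200×"; the formula's `≥` is
   the operational definition used here, so coverage exactly 200 scores.

A base covered by several windows takes the mean of its per-window scores
(NULL only when every covering window says NULL); averaging is
order-independent, which makes the reconciliation deterministic. `α`,
`window_size = 200` and `window_step = 5` are conventional icSHAPE settings
exposed as configuration, not claims about the original pipeline, which
never prints them.

The whole pipeline is ratio-based, so doubling every count leaves the
profile unchanged, and replicate order is irrelevant — both are tested
properties.

# Dataset construction

Binding peaks (BED6; column 5 is the confidence) are ranked and the top
5000 kept as positives. Each peak is fixed to 101 nt around the midpoint
`floor((start+end)/2)`, extending or trimming symmetrically with the odd
extra base on the 3' side; windows running off a transcript end are shifted
inward, and transcripts shorter than 101 nt are rejected with a logged
reason. 10000 negatives are 101-nt windows sampled uniformly without
replacement from the transcriptome; by default windows overlapping any
positive peak are excluded (configurable off — the source describes only
"random selection", but exclusion prevents label contamination). 20% of
samples form the test set and 20% of the remainder the validation set, all
splits seeded.

Sequences are tokenized into overlapping 3-mers flanked by `[CLS]`/`[SEP]`,
so a 101-nt window yields 99 interior tokens. The 101-base structure
profile is aligned to tokens by a sliding mean over each token's k bases,
ignoring missing values; tokens covering only missing bases carry the
sentinel −1. T is silently mapped to U; any other letter is an error (no
IUPAC ambiguity handling is attempted).

# The network

* **Encoder.** A pre-norm transformer with learned positional embeddings:
  token + position embeddings, then `n_layers` blocks of multi-head scaled
  dot-product self-attention (`softmax(QK'/√d_k)V`, heads concatenated
  through an output projection) and a ReLU feed-forward network, residual
  throughout, with a final layer norm. The full-size configuration is
  12 layers × 768 units × 12 heads; the desk-scale default for joint
  training is 2 × 64 × 4 with a 128-unit feed-forward (the conventional 4×
  multiplier would dominate desk-scale runtime for no accuracy gain at
  d = 64). The encoder trains jointly with the classifier by default and
  can be frozen. Internal encoder dropout is omitted at desk scale: the
  original encoder is pretrained externally, so its dropout rate is not a
  stated quantity, and omitting it keeps evaluation deterministic.
* **Unified alignment.** Sequence embeddings are reduced with 128
  one-dimensional kernels of size 1; the structure vector is upsampled with
  128 kernels of size 3. Every convolution in the network is
  Conv-BN-ReLU, bias-free, symmetrically padded to preserve length, batch
  norm momentum 0.1, dropout 0.3 after the activation (training only).
* **Multi-scale residual stage.** Four parallel branches with kernels
  1/3/5/7 stacked 1/2/3/4 blocks deep, 32 channels each, concatenated back
  to 128 channels and added to the input under a ReLU. Applied separately
  to the sequence and structure streams.
* **Fusion and pyramid predictor.** The two 128-channel maps are
  concatenated to 256 channels (addition is available as a config option).
  Then, repeatedly: two *distinct* Conv-BN-ReLU blocks (kernel 5, 256
  channels), a residual add and ReLU, and max-pooling of size 3 with stride
  2, halving the length (`ℓ → ⌊(ℓ−3)/2⌋+1`) until it reaches 1; when the
  running length drops below 3 the map is right-padded with −∞, which is
  neutral under max. For 99 tokens the trajectory is
  99→49→24→11→5→2→1 (six stages, each with its own parameters). A one-unit
  dense layer and sigmoid produce the binding probability.

The layer library underneath (linear, embedding, layer norm, attention,
im2col convolution, batch norm, dropout, max-pool) is implemented directly
on BLAS matrix products with handwritten backpropagation, because no deep
learning framework exists in the supported environment. Every layer's
analytic gradient is verified against central finite differences in the
test suite, including one end-to-end check through the entire network.

# Training

Adam (batch 32, learning rate 0.001, weight decay 1e−6) with a linear
warm-up of the learning rate over the first epoch's steps, early stopping
on validation loss (patience 5 epochs by default) and restoration of the
best-validation checkpoint including batch-norm running statistics. The
objective is mean binary cross-entropy; the L2 penalty `λ|W|₂` is realized
once, through the optimizer's weight decay, to avoid double regularization
(the explicit form is available in `bce_l2_loss()` for verification).
Probabilities are clamped at 1e−7 in the loss. Initialization is Kaiming
for convolutional/dense weights. Training is a pure function of the seed:
identical seeds give identical histories. Warm-up horizon and patience are
configuration, as the source prints neither.

# Interpretation

* **Motif calling.** Maximal runs of tokens whose attention score (1)
  strictly exceeds the sequence mean and (2) is at least 10× the floor
  score become fragments; a token run `[a, b]` spans nucleotides
  `[a, b+k−1]`, and fragments shorter than 6 nt are discarded. The floor is
  `max(min(att), 1e−8·max(att))`: with a raw minimum of zero the printed
  "10× the lowest score" rule would be vacuous.
* **Attention sources.** Two per-token attention definitions are
  implemented. The *encoder* source is the CLS-row softmax weight summed
  over heads, read from the final layer (averaged when several layers are
  requested; the reading layer is not stated in the source). The *gradient*
  source is expected-gradients attribution of the output logit over the
  model input, reduced per token by the maximum over all input feature
  dimensions — embedding dimensions and the structure channel jointly —
  with 16 seeded shuffled-sequence baselines by default. Before the motif
  criteria are applied, high-attention segments are located with a sliding
  window: a centered moving average of 5 tokens (edge-replicated,
  configurable, 1 = off) aggregates the per-token attribution so that a
  sharp peak still yields a contiguous qualifying run — fewer baselines or
  no aggregation leave the vector too noisy and spiky for stable fragment
  calls. The gradient
  source is the default for motif calling on trained models: meaningful
  CLS attention in the encoder family rests on large-scale masked-language
  pretraining, which is out of scope here, and a from-scratch desk-scale
  encoder can separate classes without focusing its CLS attention (uniform
  attention over value vectors is already linearly separable), so its
  Eq-33-style attention localizes planted motifs only unreliably. The
  gradient definition is the one the source's own visualization procedure
  uses to build its length-99 attention vector.
* **PWMs.** Called fragments are reduced to the modal length by symmetric
  trimming (shorter fragments are dropped; no gapped alignment), counted
  per position and normalized, with an optional pseudocount (default 0).
  Output in MEME minimal format.
* **Saliency spreading.** The five-case rule mapping a 99-long token
  attention vector to 101 nucleotide scores is implemented exactly as
  printed, including the `i = 100` case that omits `Att_i`. At `i = 101`
  the printed index (`Att_100`) exceeds the vector, so it is clamped to
  `Att_99`, the last token covering base 101. The map is linear and
  constant-preserving, both tested.
* **Variant effect.** A substituted base re-tokenizes at most k tokens;
  the model re-embeds and re-predicts, reporting `ΔP = P_alt − P_ref`. The
  structure vector is reused unchanged: re-estimating the variant's
  structure would require new probing data.

# Synthetic data: what it does and does not establish

The generators produce (i) uniform random transcriptomes, (ii)
confidence-ranked random peak sets, (iii) planted-motif datasets in which
positives carry a fixed motif (default `UGCAUG`, a classic 6-nt RBP motif)
at a uniform offset with single-stranded-like reactivity inside the motif
(mean 0.9) against a background of 0.3, clipped-normal noise 0.15, and
(iv) Poisson count tables for a known reactivity truth (base density
~ Poisson(depth); NAI RT-stops ~ Poisson(depth·(0.1 + truth)); DMSO
~ Poisson(depth·0.1); the 0.1/1.0 background/gain are fixture choices).
All generators are pure functions of the seed.

These emulate the statistical skeleton the method assumes — sequence motif
plus structural preference — not real data: there is no transcript
abundance structure, no positional bias in peaks, no correlated probing
noise, and negatives are uniform background. A green end-to-end test
therefore establishes that the implementation can learn and localize a
planted signal at the stated sizes, not that it reaches any published
benchmark accuracy; the published numbers require external CLIP/icSHAPE
datasets and a pretrained encoder, which are explicitly out of scope.

On the default synthetic world the trained model relies mostly on the
structure channel (flattening structure collapses accuracy; shuffling
sequence does not), which is why the structure-only ablation experiment in
the acceptance suite separates the structure-aware model from a
sequence-only one.

# Numerical choices and degenerate inputs

* Probability clamp 1e−7 in the loss; batch-norm ε 1e−5; layer-norm ε 1e−5.
* Quantiles are R type-7 (linear interpolation).
* A window whose enrichment anchors coincide (`e_q95 = e_q05`) maps all
  defined bases to 0 rather than dividing by zero.
* Max-pool ties take the earliest tap, making pooling deterministic.
* Transcripts shorter than the icSHAPE window are processed as one window;
  the final window is anchored at the 3' end so every base is covered.
* `fixed_samples` recycles a scalar label; any other length mismatch is an
  error.
* Checkpoints store parameters, configuration and batch-norm running
  statistics; evaluation is deterministic (dropout off, running stats).

# Known limitations

* The encoder is trained from scratch; no pretrained weights ship with the
  package, and CLS attention should not be expected to match
  pretrained-encoder attention maps (see Interpretation).
* The pyramid stage count is fixed by the configured sample length; inputs
  whose pooling schedule is longer reuse the final stage's parameters.
* PWM building drops fragments shorter than the modal length instead of
  aligning them with gaps.
* Single-CPU, double-precision only; no GPU path.
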