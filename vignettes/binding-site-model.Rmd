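---
title: "The bindsite model: feature space, network, training and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bindsite model: feature space, network, training and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindsite)
```

`bindsite` labels every residue of a protein sequence as ligand-binding or
not, using a deep, fully convolutional classifier over a 30-dimensional
per-residue feature embedding. This vignette is the package's account of
the model: what it assumes, which knobs matter, the numerical choices
made where the design was genuinely open, and what the synthetic
benchmarks do and do not demonstrate.

## The residue feature space

Each residue is embedded in d = 30 dimensions, in this fixed column
order:

| columns | feature | transform |
|---|---|---|
| 1–20 | PSSM log-odds | `y = 1/(1 + 2^(-x))`, strictly into (0, 1) |
| 21 | relative solvent accessibility | kept as given (fraction in [0, 1]) |
| 22–24 | helix / strand / coil propensities | kept as given, each in [0, 1] |
| 25–26 | φ / ψ dihedrals (degrees) | divided by 360 |
| 27–28 | conservation (RE, JSD) | kept as given |
| 29 | residue type | index / 21 |
| 30 | position | i / L, 1-based |

Choices that the inputs themselves do not fix:

* **Residue-type index table.** The 20 standard one-letter codes in
  alphabetical order receive indices 0–19 and the dummy (padding) residue
  `X` receives 20; the feature is `index/21`. The table is frozen — a
  different ordering would train equally well but checkpoints would not be
  interchangeable.
* **Position embeddings are 1-based**, so values lie in (0, 1] and the
  final residue is exactly 1; no residue sits at exactly 0.
* **Negative dihedrals pass through** `x/360` unchanged, giving values in
  (−0.5, 0.5] for the conventional (−180, 180] range. An optional
  `wrap = TRUE` first maps angles to [0, 360). Wrapping is off by default
  because the discontinuity it introduces at 0°/360° is worse for a
  convolutional model than a sign.
* **RSA is not binarized.** The common 25% buried/exposed cut discards
  information; the real value is retained.
* **Conservation scores use base-2 logarithms**, which bounds the
  Jensen–Shannon divergence by 1 and keeps both scores on comparable
  scales. `conservation_scores()` is a convenience; precomputed scores in
  a feature table are consumed verbatim.

## The network

The encoder lifts the `m × 30` feature map to `2c` channels with one
width-`k` convolution, then applies `n_stages` stages of `N` blocks each.
A block computes per-residue LayerNorm, a gated linear unit
(`A ⊗ σ(B)` over a channel split, halving `2c` to `c`), and a width-`k`
convolution back to `2c` channels, with a residual connection around the
whole block. Because every layer preserves the sequence length, `n`
stacked width-`k` convolutions give each output an input field of exactly
`1 + n(k − 1)` residues: depth, not a window parameter, sets the maximum
dependency length. Defaults follow the locally optimal operating point of
the approach: `k = 5`, `N = 10`, `c = 256`, two stages, dropout 0.5.

Where the architecture description leaves room, the package commits to:

* **Plain-block placement.** Each stage opens with a Plain block (same
  LN–GLU–Conv body, no residual) followed by `N − 1` residual blocks.
  Putting the non-residual block first gives the stage one clean channel
  re-mixing step before the residual chain accumulates.
* **Stage tops.** The "additional layers to stabilize gradients and
  normalize outputs" at the top of each stage are realized as a single
  LayerNorm with learned gain and offset.
* **GLU split convention.** The first `c` channels are the linear part
  `A`, the last `c` the gate `B`.
* **LayerNorm axis and ε.** Normalization is per residue over channels
  with `ε = 1e-5` and learned gain/offset.
* **Configurable stage count.** `n_stages` defaults to 2 but is a
  parameter: receptive-field experiments need encoders whose total
  conv-layer count `1 + n_stages·N` can be set freely (the two-stage
  count is always odd).
* **Even kernel widths are rejected** at configuration time; the
  symmetric `(k − 1)/2` zero-padding that keeps `m` fixed requires odd
  `k`.
* **Initialization** is variance-scaling Gaussian (sd `1/sqrt(fan_in)`)
  for kernels, zeros for biases and LayerNorm offsets, ones for gains,
  drawn from the session RNG so runs are seedable.

### Decoders

The standard head applies 1×1 convolutions `2c → c → 2` (dropout wraps
the first during training), drops dummy-residue rows, and applies a 2-way
softmax.

The enhanced head additionally transforms the `m × 2` context prediction
through two branches. Each branch shifts the context by one position
(dropping the last element for the left-context branch, the first for the
right), pads `k` zeros on the leading side, lifts to `2c` channels with a
`k × 2` convolution, and runs a causal stage of `M` blocks (default
`M = 2`) topped by LayerNorm; all in-branch convolutions are one-sidedly
padded so the branch stays causal. Both branch outputs are added to the
encoder output before the standard head. The shift guarantees that the
left branch's output at position `i` depends only on context at positions
strictly before `i` (mirrored on the right), so a residue never sees its
own label during teacher forcing. Context is encoded as the two class
scores: one-hot labels during training, first-pass softmax probabilities
at the second inference pass, and a zero tensor at the first pass — the
zero context also plays the role of start/end marks, since the shift-and-
pad scheme feeds zeros beyond the sequence ends.

### Masking and padding

Sequences in a batch are padded to the batch maximum with dummy-residue
rows, and a validity mask accompanies every padded map. Masked rows are
zeroed immediately before every convolution, which makes trailing padding
indistinguishable from the zero-padding a lone sequence receives; the
rows themselves are dropped just before the softmax. The consequence,
verified by test, is exact invariance: per-residue probabilities and the
loss are identical whatever the padding amount or batch composition.
Without the masking step, dummy rows would leak into the receptive field
of real residues near the sequence end and predictions would depend on
batch grouping.

A numerical footnote: LayerNorm is non-differentiable at an exactly
constant input row (variance 0). With zero-initialized biases the context
branches sit at such a point for all-zero context windows; the forward
pass is exact there (the normalized value is 0) and the backward pass
returns the bounded one-sided derivative, so training simply steps off
the point. Gradient tests therefore probe at a generic point; the
analytic gradients match central finite differences to ~1e-9 relative
error.

## Training

The objective is the cross-entropy over valid residues plus
`γ · ‖θ‖²`. Choices:

* **Mean reduction** over valid residues per batch (a `"sum"` option
  exists). The mean keeps the gradient scale — and hence a given `γ` —
  stable across batch sizes and sequence lengths.
* **The L2 penalty covers convolution/projection kernels only.**
  LayerNorm gains/offsets and biases are excluded: shrinking a gain
  toward zero is not a meaningful prior, and penalizing offsets fights
  the class prior the decoder must express under 3% positives.
* **No resampling or reweighting, ever.** Whole sequences are the batching
  unit, so every mini-batch carries approximately the natural skew; the
  network must learn the imbalanced problem as posed.
* **Optimizer.** Plain mini-batch gradient descent is the default; Adam
  is available as an option, and an optional global-norm gradient clip
  exists for the steep early-training phase (off by default).
* **Three-stage learning schedule.** Within a stage the rate is
  `init · decay^floor(elapsed/interval)`; stage boundaries reset to the
  next stage's initial rate, and the second stage's initial rate may
  exceed the first's final rate — the escape stage exists because the
  skewed objective has a strong all-negative local minimum that a timid
  rate cannot leave. The shipped default stages (0.05/0.15/0.02 over
  300/900/300 iterations) encode the preheat/escape/finish shape;
  every training run in the tests and the acceptance script pins its own
  stage values, scaled to its problem size. A practical caution observed
  while tuning with Adam: because Adam's steps are rate-sized regardless
  of gradient magnitude, an aggressive escape stage can also *destroy* an
  already-converged fit and land it in the all-negative minimum — with
  Adam the escape stage should be gentle (a small multiple of stage 1).

Enhanced training loads all standard-model weights, freezes the encoder
(bit-identical before and after, also verified by test), initializes the
context branches, and fine-tunes the decoding head and branches under
teacher forcing with one-hot label context, so training parallelizes over
the sequence. Since the encoder is frozen, its outputs are precomputed
once per protein rather than re-run each iteration.

## The synthetic corpus generator

The generator exists so that every mechanism — feature pipeline, masking,
training, both decoders, evaluation — is exercisable end-to-end with no
external feature predictors. It emulates the statistical structure the
method is designed for:

* **Class skew**: target positive fraction 0.03 by default, the regime of
  curated binding-residue benchmarks (at most ~4% positives).
* **Variable lengths**: uniform in `length_range` (default 80–300,
  typical of single-domain ligand-binding chains). Each protein draws
  from its own seeded RNG stream, so corpora that differ only in rule
  parameters share lengths protein-by-protein.
* **Planted label rules.** A local motif rule (a trigger residue, W, is
  itself binding) and a long-range pair rule (residue `i` binds iff the
  trigger C sits at `i − D` or `i + D`). Background letters exclude
  active triggers, so every positive is attributable to a planted rule;
  positives are planted in geometric-length runs (mean `clustering`,
  default 3) to mimic the aggregation of binding residues along the
  sequence that the enhanced decoder exploits.
* **Features are generated in raw space** (log-odds, degrees, raw
  scores), so the full normalization pipeline is exercised. The PSSM
  emulates a profile matrix: the residue's own log-odds are centred at
  +5 and the remaining entries at −1 (noise sd 1), matching the strong
  self-match signal real profiles carry — the query sequence is part of
  the profile, so the residue identity is essentially always recoverable
  from its column. Label-correlated signal is added on top of the PSSM
  and conservation channels with strength `snr_pssm` / `snr_cs`; RSA,
  secondary structure and dihedrals are label-independent noise.

`receptive_field_challenge()` builds pair-rule-only corpora across a set
of distances `D` with **zero** label-correlated feature signal: the only
route to the label is seeing the trigger `D` positions away, so held-out
accuracy directly measures whether the model's input field spans
`2D + 1`. With any label-correlated local signal left in, a model whose
field is too small could still beat chance and the contrast would be
meaningless.

What passing these benchmarks does *not* show: real PSSMs have
position-dependent, inter-column-correlated distributions; real binding
sites follow ligand chemistry, not token rules; and real labels are
noisy. Synthetic results demonstrate mechanism (capacity, receptive-field
control, context decoding, masking correctness), not expected accuracy on
biological data.

## Evaluation conventions

* Metrics are micro-averaged: residues are pooled across proteins before
  counting, matching single-MCC reporting per test set.
* MCC with any zero factor in the denominator is defined as 0.
* Precision/recall with a zero denominator return 0 and are flagged
  degenerate.
* The dataset audit reports `P_BR = 100 · BR/NBR` rounded half-up to two
  decimals. The ratio is against the *non-binding* count — this is the
  convention that reproduces every value printed in the field's benchmark
  summary tables, although the column is usually labeled a "proportion";
  `BR/(BR + NBR)` does not reproduce them.
* The default decision threshold is 0.4; `threshold_sweep()` reports the
  0.1–0.9 grid, along which the predicted-positive count and recall are
  non-increasing by construction.

## Problem sizes

The shipped tests and the acceptance script run reduced configurations
chosen to exercise every mechanism at desk scale: channels 8–16, two
stages of 2 blocks, `k = 3`, corpora of 20–200 proteins of length 40–120,
and schedules of 800–1,600 iterations. These sizes are the package's
choice of smallest-convincing experiment: the capacity check saturates,
the within-field/beyond-field contrast is near-maximal, and the whole
suite stays inexpensive. The default `network_config()` reflects the
full-scale operating point and trains the same way, only slower.

## Known limitations

* Pure-R training: practical for the reduced configurations above; the
  full 512-channel, 20-block configuration on thousands of proteins would
  want weeks of CPU time and is out of intended scope.
* The enhanced decoder's two-pass inference is implemented; the fully
  serial left-to-right decoding alternative it approximates is not.
* No per-ligand-type stratified metrics; residues are pooled.
* Feature generation from real sequences (profile search, accessibility
  and secondary-structure prediction) is upstream of this package; it
  consumes their outputs via the feature-table format.
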