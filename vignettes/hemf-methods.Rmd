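---
title: "Hierarchical multi-attention feature fusion: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multi-attention feature fusion: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemf)
```

## The problem and the model

Medical image classification (skin lesions, endoscopy frames, CT slices)
is hard because classes share global appearance while differing in subtle
local texture. Pure convolutional networks capture local detail but little
long-range context; pure attention models capture context but disrupt
fine-grained structure. The HEMF architecture implemented here runs the
two families **in parallel** and fuses them at every scale:

* a **stem** (4×4 convolution, stride 4, 3 → 96 channels, channel
  layer normalization) turns a 224×224×3 image into a 56×56×96 map;
* four **stages** operate at 1/4, 1/8, 1/16 and 1/32 resolution with
  widths 96/192/384/768. In each stage a *local branch* applies four
  stacked conv blocks and a *global branch* three attention blocks, both
  preceded by one stage-entry layer normalization; between stages each
  branch is downsampled by LN + 2×2/stride-2 convolution that doubles the
  channels (the two branches do **not** share downsampling weights);
* a per-stage **fusion block** combines the two branch outputs with the
  previous fusion output;
* a head (global average pooling → LN → linear) emits the class logits.

### Local blocks (ELF)

Each local block computes

$$l = \mathrm{LN}(f^{3\times3}(x)), \qquad
  y = \mathrm{GELU}(f^{1\times1}(f^{\mathrm{depth}\,3\times3}(l))) + x .$$

Both 3×3 convolutions use padding 1 so the skip connection is well-typed.
Layer normalization is *channels-last per spatial position* (each pixel's
channel vector is normalized), the convention of modern conv backbones;
GELU is the exact erf form \(x\,\Phi(x)\).

### Global blocks (EGF) and Manhattan self-attention

The global branch uses decayed softmax attention (MaSA): with tokens the
spatial positions enumerated row-major (x inner, 0-based coordinates),

$$\mathrm{MaSA}(X) = \big(\mathrm{Softmax}(QK^{\mathsf T}/\sqrt{d_h})
  \odot D^{2d}\big)V, \qquad
  D^{2d}_{nm} = \gamma^{\,|x_n - x_m| + |y_n - y_m|},$$

so attention decays geometrically with the Manhattan distance between
positions, injecting an explicit spatial prior. Notes on choices the
formula leaves open:

* the score scaling \(1/\sqrt{d_h}\) is universal attention practice and
  is included deliberately;
* per-head decays follow the retentive-network schedule
  \(\gamma_h = 1 - 2^{-(5+h)}\), \(h = 0,\dots,H-1\)
  (`masa_gamma_schedule()`); head counts default to width/32, i.e.
  3/6/12/24 across the stages;
* the full \(N \times N\) decay mask is the reference implementation —
  decomposed axial variants are approximations and are not used;
* position information enters once per stage as a conditional positional
  embedding, `x + depthwise3x3(x)`, before the first block only.

The block wiring is
`g = LN(MaSA(PosEmb(x)) + PosEmb(x))`, `out = LN(Linear(g) + g)`.

### Mixed attention

Fusion first re-weights each branch with a three-part gate:

$$m_x = \mathrm{LN}(\mathrm{MHEA}(\mathrm{LN}(x)) \times \mathrm{LN}(x)),
\quad m_y = m_x \times \mathrm{SA}(m_x),
\quad \mathrm{out} = m_y \times \mathrm{CA}(m_y).$$

Multi-head **external attention** scores tokens against small learnable
memories \(M_k, M_v \in \mathbb{R}^{S\times d}\) per head and applies
*double normalization*: softmax over the token axis per memory slot, then
L1 normalization over the memory axis per token. The resulting weights
are nonnegative with unit row sums, so every output token is a convex
combination of memory rows — an invariant the tests assert. The
**spatial** gate is `sigmoid(conv7x7(concat[channel-mean, channel-max]))`
and the **channel** gate is `sigmoid(MLP(avgpool) + MLP(maxpool))` with a
shared C → C/16 → C perceptron (ReLU inside, the convention of the
attention-gate literature). The inner `LN(x)` of the first equation is
one normalization evaluated once and used twice. Memory size defaults to
S = 64 per head, the established external-attention default.

### Fusion block (HEF) and the squeezed inverted residual MLP

With \(L_i, G_i\) the branch outputs and \(\mathrm{HEF}_{i-1}\) the
previous fusion output,

$$h_x = \mathrm{AvgPool}_{2\times2}(f^{1\times1}_{\times2}(\mathrm{HEF}_{i-1})), \quad
  h_y = \mathrm{GELU}(f^{1\times1}_{3C\to C}(\mathrm{LN}(
        [\,h_x, f^{1\times1}(L_i), f^{1\times1}(G_i)\,]))),$$
$$\mathrm{HEF}_i = \mathrm{SIRMLP}(\mathrm{LN}(
  [\,\mathrm{MixAttn}(G_i), \mathrm{MixAttn}(L_i), h_y\,])) + h_x .$$

At stage 1 there is no previous fusion output; the stem output takes its
place through a channel-preserving 1×1 projection without pooling. The
"dim" bookkeeping is resolved so that every stage type-checks: the
concatenation has 3C channels, SIRMLP squeezes 3C → C, expands C → 4C,
and reduces 4C → C, so the `+ h_x` skip is always well-typed:

$$s_x = \mathrm{BN}(f^{1\times1}_{3C\to C}(x)), \quad
  s_y = \mathrm{BN}(\mathrm{GELU}(f^{\mathrm{depth}\,3\times3}(s_x)) + s_x), \quad
  \mathrm{out} = \mathrm{BN}(f^{1\times1}_{4C\to C}(
      \mathrm{GELU}(f^{1\times1}_{C\to 4C}(s_y)))).$$

Squeezing *before* the inverted-residual expansion is what makes the
block cheap: the closed-form trainable-parameter counts are

* SIRMLP: \(11C^2 + 22C\),
* inverted-residual MLP operating directly on the 3C input
  (depthwise 3×3, expand ×4, linear back): \(72C^2 + 45C\),

a reduction of \(1 - \frac{11C^2+22C}{72C^2+45C} \to 1 - 11/72 \approx
84.7\%\), and between 84.5% and 84.7% at the four stage widths. Both
forms are verified against enumeration of constructed blocks in the test
suite, and `profile_table()` exposes the comparison per stage.

## Parameter and FLOP accounting

`count_parameters()` is an analytic sum over layer shapes, checked
against enumeration of an instantiated model. `count_flops()` counts
multiply-accumulates (1 MAC = 1 FLOP, stated in the CSV header because
published counters differ by ×2): convolutions as
\(k^2 C_\mathrm{in} C_\mathrm{out} H W / \mathrm{groups}\), linears as
\(n\,d_\mathrm{in} d_\mathrm{out}\), attention as \(N^2 d\) per head for
both the score and value products, external attention as \(N S d\) per
head per product; elementwise work, normalizations, softmax and pooling
are excluded. Under these rules the default 7-class model at 224² costs
59.90M parameters and 15.42G MACs. Two caveats worth stating explicitly:

* self-attention over the 56×56 grid (3136 tokens) alone contributes
  about 5.7G MACs; module-hook profilers that only see registered layers
  (and miss functional matrix products) would report roughly 8.9G for
  this architecture, so cross-tool comparisons of the FLOP total depend
  heavily on the counting convention;
* several width-determining hyperparameters of the original design
  (external-attention memory size, head counts, the exact expansion
  bookkeeping) are not uniquely determined, so absolute totals carry a
  reconstruction uncertainty of roughly ±15%, while the SIRMLP-vs-IRMLP
  decline ratio is insensitive to all of them.

## The computational engine

No deep-learning framework is used: the package carries its own
tape-based reverse-mode automatic differentiation engine over
`[batch, channel, height, width]` arrays (`R/autograd.R`), with im2col +
GEMM convolution kernels, channel layer normalization and exact GELU in
compiled code (`src/ops.cpp`). Both attention mechanisms are single
composite tape entries with hand-derived backward passes. Every
primitive and every block is validated against central finite
differences (relative error ≤ 1e-5 at probe points); the two attention
forwards are additionally checked against explicit-loop oracles that
evaluate the defining formulas term by term.

Numerical conventions: double precision throughout; LN eps 1e-6; BN eps
1e-5 and momentum 0.1 with running statistics (training mode uses batch
statistics, evaluation mode the running ones); softmax and
cross-entropy use max-subtraction / log-sum-exp stabilization; channel
max-pooling breaks ties by first index. The `mixed_precision` flag is
accepted for interface compatibility but computation stays in double
precision and the flag is excluded from determinism guarantees.

## Training recipe

`train_config()` defaults encode the recipe field for field: AdamW
(β₁ = 0.9, β₂ = 0.999, eps = 1e-8, decoupled weight decay 0.01), initial
learning rate 1e-4, final 1e-6, linear warmup over the first epoch
starting at 1/100 of the initial rate (the warmup shape is otherwise
unconstrained; the start factor is this package's choice), then cosine
annealing that reaches exactly 1e-6 at the final step; 150 epochs, batch
size 32, categorical cross-entropy, drop-path 0 (a hook exists but only
0 is accepted). Best-checkpoint selection uses validation accuracy when
a validation split exists, else training loss. Gradient clipping is off.
Runs are bitwise reproducible given the seed.

## Synthetic data: what it emulates and what it does not

`generate_synthetic_dataset()` emulates class-labelled medical-image
folders with class-dependent parametric textures: each class has a
distinct oriented stripe frequency, blob count, base intensity and
colour tint, plus i.i.d. Gaussian pixel noise (default sd 0.05) and a
random phase/blob layout per image. The defaults separate the
class-conditional mean intensity by at least five noise standard
deviations, so the labels are learnable by construction — a depth-1
stump on mean intensity already exceeds 95% accuracy, which is what
makes the overfitting smoke test well-posed. An optional per-class count
vector reproduces long-tailed label distributions (e.g. a 6075:…:115
seven-class imbalance at 1/10 scale). What the generator does **not**
emulate: intra-class style variation, acquisition artefacts, inter-class
feature overlap, or any spatial semantics of real lesions — passing the
training tests therefore demonstrates that the architecture, gradients
and optimizer work, not that the model generalizes on real data.

## Problem sizes used by the test suite

Unit tests run on widths 8–64 at 16–32 px. The learning smoke test
trains the package's **compact configuration** — the identical topology
(stem, four dual-branch stages with 4 conv + 3 attention blocks,
per-stage fusion with both mixed-attention gates, the same head) at
widths 16/32/64/128 with heads 1/2/4/8 and memory 16 — on the standard
smoke conditions (2 classes × 32 images, 64×64, noise sd 0.05, batch 32,
≤ 200 optimizer steps). The width scaling is the package's choice of a
desk-scale instance for its double-precision CPU engine; the recipe
itself is unchanged. Full-width geometry and accounting are still
exercised: the acceptance tests run one complete 224² forward pass at
widths 96/192/384/768 and verify every stage shape.

## Known limitations

* CPU-only and double precision; throughput is orders of magnitude below
  GPU frameworks, so full-resolution training at the default widths is
  out of reach — the package targets architectural fidelity, correctness
  and desk-scale experiments, not large-scale training.
* The full decay mask costs O(N²) memory per head; at 224² inference
  stage 1 transiently holds ~80 MB per head-sample.
* No data augmentation is built in (by design of the recipe); an
  optional flip could be added but defaults would stay off.
* Checkpoints are R-native serialized objects; no cross-framework
  export.
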