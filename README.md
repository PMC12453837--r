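# hemf

Hierarchical enhanced multi-attention feature fusion for medical image
classification, implemented from scratch in R.

Medical images (dermoscopy, endoscopy, CT slices) mix subtle local texture
with global context. This package implements a hierarchical CNN–transformer
hybrid classifier that extracts both in parallel and fuses them at every
scale: a 4×4/stride-4 stem, four dual-branch stages (four convolutional
blocks beside three Manhattan-self-attention blocks per stage, widths
96/192/384/768 at 1/4…1/32 resolution), a per-stage fusion module built
from a mixed attention gate (multi-head external attention × spatial gate ×
channel gate) and a squeezed inverted residual MLP (SIRMLP), and a
GAP → LN → linear head.

The attention core is **Manhattan self-attention**: softmax attention whose
weights are damped by a spatial decay mask,

    MaSA(X) = (Softmax(Q Kᵀ / √d) ⊙ D) V,   D[n,m] = γ^(|xₙ−xₘ| + |yₙ−yₘ|),

and the fusion core is the **SIRMLP**, which squeezes the three-branch
concatenation 3C → C before the inverted-residual expansion — cutting the
block's parameters by ≈ 84.5% relative to an inverted residual MLP applied
to the 3C input (closed forms `11C² + 22C` vs `72C² + 45C`).

Because no deep-learning framework ships with this toolchain, the package
includes its own tape-based reverse-mode autodiff engine over
`[N, C, H, W]` arrays with compiled (RcppArmadillo) convolution and
normalization kernels, an AdamW training loop with linear-warmup + cosine
annealing, a synthetic labelled-texture image generator, multiclass metrics
(accuracy, macro precision/recall/F1, MCC, Cohen's kappa, one-vs-rest
ROC/AUC), a parameter/FLOP profiler, and a CLI.

## Worked example

Generate a small two-class synthetic dataset, train a compact (CPU-sized)
instance of the architecture for a few steps, and evaluate:

```r
library(hemf)

spec <- synthetic_spec(num_classes = 2, images_per_class = 32,
                       image_size = 64, noise_sd = 0.05, seed = 11)
ds <- generate_synthetic_dataset(spec)
train <- list(images = normalize_images(ds$images), labels = ds$labels)

cfg <- hemf_config(num_classes = 2, input_size = 64,
                   stem_width = 16, stage_widths = c(16, 32, 64, 128),
                   masa_heads = c(1, 2, 4, 8), mhea_heads = c(1, 2, 4, 8),
                   ea_memory = 16)
fit <- train_model(cfg, train_config(epochs = 100, seed = 42), train,
                   max_steps = 200, stop_when_acc = 0.95)
fit$history[, c("epoch", "lr", "train_loss", "train_acc")]
#>   epoch           lr train_loss train_acc
#> 1     1 1.000000e-04   0.583427  0.859375
#> 2     2 9.999371e-05   0.211881  1.000000

evaluate_model(fit$model, train)
#> accuracy 1.0000  macro P 1.0000  R 1.0000  F1 1.0000
#> MCC 1.0000  kappa 1.0000  macro AUC 1.0000
```

The model reaches 100% training accuracy after four optimizer steps: the
synthetic classes differ in base intensity and stripe texture by
construction, so an architecture with working gradients overfits 64 images
almost immediately. The learning rate shown follows the recipe: linear
warmup to 1e-4 over the first epoch, then cosine decay toward 1e-6.

Architecture accounting for the full-size model:

```r
profile_table(hemf_config(num_classes = 7))
#> Per-stage fusion block comparison (params exact, FLOPs = MACs):
#>  layer     input_shape sirmlp_params irmlp_params decline_pct ...
#>      1  [96x3, 56, 56]        103488       667872    84.50482
#>      2 [192x3, 28, 28]        409728      2662848    84.61317
#>      3 [384x3, 14, 14]       1630464     10634112    84.66761
#>      4   [768x3, 7, 7]       6504960     42501888    84.69489
#> Total parameters: 59902867 (59.90M)
#> Total forward MACs (1 MAC = 1 FLOP): 15420097492 (15.42G)
```

(The decline column is the SIRMLP-vs-IRMLP parameter reduction per stage;
its mean, 84.62%, is the robust efficiency figure. The absolute totals
carry a ±15% reconstruction uncertainty discussed in the methods
vignette.)

## Command line

A thin wrapper lives at `inst/cli/hemf` (all logic is in the package):

```sh
Rscript -e 'library(hemf); quit(status = cli(commandArgs(TRUE)))' \
  synth --out data/demo --classes 2 --per-class 32 --size 64 --seed 1
# subcommands: synth | train | eval | info | splits
```

`info --classes 7` prints the stage geometry (56,96) … (7,768), total
parameters and MACs, and can write the per-stage profile CSV.

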