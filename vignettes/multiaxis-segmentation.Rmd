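---
title: "Multi-axis attention segmentation: model, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-axis attention segmentation: model, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
segmentation network, the evaluation metrics, the synthetic-data generator,
and the numerical and design choices made where more than one reasonable
reading existed.

## The model

The network is a U-shaped encoder–decoder for 2D medical images (CT/MRI
slices replicated to three channels, or RGB endoscopy) whose stages mix
convolution and *multi-axis self-attention*. Attention over all $H \times W$
positions costs $O((HW)^2)$; multi-axis attention replaces it by two cheap,
complementary windowed passes:

* **Block attention** partitions the map into non-overlapping $P \times P$
  tiles and attends within each tile — a local operator.
* **Grid attention** splits $H$ into $(G, H/G)$ and $W$ into $(G, W/G)$ and
  attends among the $G^2$ positions that share an intra-cell offset — a
  dilated, global operator whose tokens are spread across the whole map.

Both use relative-position attention within each token group,

$$\mathrm{RelAttention}(Q, K, V) = \mathrm{softmax}\!\left(QK^\top/\sqrt{d} + B\right)V,$$

where $B$ is looked up from a learned table with one entry per 2D offset —
$(2P-1)^2$ entries per head — so the largest attention matrix ever
materialised is $P^2 \times P^2$ regardless of image size (linear overall
cost). One *attention block* applies, in sequence, pre-norm block attention
with a residual, a position-wise MLP ($W_2\,\mathrm{GELU}(W_1 x)$, expansion
4) with a residual, then the same pair again with grid attention.

The encoder stem is a 3×3 stride-2 convolution to 64 channels followed by a
3×3 convolution. Four stages then repeat (2, 2, 5, 2) units, each unit an
MBConv followed by an attention block. The MBConv is an inverted bottleneck:
BatchNorm, 1×1 expansion (4×, +BN+GELU), 3×3 depthwise convolution
(+BN+GELU), squeeze–excitation (bottleneck a quarter of the expanded width),
and a 1×1 projection, added residually. The first unit of each stage uses a
stride-2 depthwise convolution with a pooled-and-projected shortcut,
`Proj(AvgPool(x)) + Proj(SE(DWConv_s2(Conv(Norm(x)))))`, halving the extent
and doubling the width: 224² inputs flow through 56²×64, 28²×128, 14²×256,
7²×512.

The decoder mirrors the encoder with *patch-expanding* upsampling: a linear
channel expansion followed by depth-to-space rearrangement, doubling the
extent while halving the channels; a final 4× expansion restores the input
resolution before a 1×1 classification head emits per-pixel logits.

### Attention-gated skips

Plain skip connections forward encoder noise along with detail. The package
gates them:

* the **bottleneck** (deepest) features pass through a CBAM — a channel gate
  $\sigma(\mathrm{MLP}(\mathrm{avg}) + \mathrm{MLP}(\mathrm{max}))$ with a
  shared bottleneck MLP ($r = 16$, ReLU inside), then a spatial gate
  $\sigma(f^{7\times7}[\mathrm{avg}_c; \mathrm{max}_c])$;
* each skip at stages 1–3 passes through the **multi-scale gate**: the
  channel weights come from the *deeper* stage ($2C_0$ channels, pooled to
  two descriptors, shared 1×1 map to $C_0$, summed, sigmoid), the spatial
  weights from the *shallower* stage (7×7 stride-2 convolution to one
  channel, BatchNorm, sigmoid), and both multiply the current stage's map:
  $F_0'' = M_s(F_1) \otimes (M_c(F_2) \otimes F_0)$. Stage 1 has no earlier
  attention stage, so the stem output serves as its shallow input.

Fusion itself is concatenation followed by a learned 1×1 projection back to
the decoder width (an additive mode is available behind
`fuse_mode = "add"`).

### Ablation flags

`skip_mode` (`"mcbam"`, `"cbam"`, `"none"`) and `downsample_mode`
(`"mbconv"`, `"plain_conv"` — every MBConv replaced by a single 3×3
convolution) express the ablation grid purely through configuration; the
parameter sets nest in the expected order (multi-scale gates ⊃ CBAM gates ⊃
no gates).

## Parameter accounting and the decoder reading

The base configuration counts **40.52 M** trainable parameters. Two points
of the accounting were genuinely open:

* **Stage-1 width.** The stem emits 64 channels at half resolution and the
  doubling rule is applied *between* stages, giving widths (64, 128, 256,
  512). The alternative reading (doubling already at stage 1) yields an
  8C = 1024 bottleneck and roughly twice the parameters — incompatible with
  the ~40 M budget this architecture family reports.
* **Decoder units.** In the MaxViT lineage a "block" is MBConv + block
  attention + grid attention; a decoder "built from the same blocks" then
  carries a (non-downsampling) MBConv in every decoder unit. Attention-only
  decoder units would count 37.71 M. The composite reading lands within
  0.6 % of the published count and is the default
  (`decoder_mbconv = TRUE`); the attention-only topology remains available
  behind the flag. Decoder depths are (2, 2, 2): "symmetric" is read as
  symmetry of block type and stage structure, not per-stage repeats — a
  5-deep decoder stage at width 256 would add ~4.7 M parameters and
  overshoot the budget.

## Metrics

For binary masks $X$ (prediction) and $Y$ (truth):

$$\mathrm{DSC} = \frac{2|X \cap Y|}{|X| + |Y|}, \qquad
  \mathrm{IoU} = \frac{|X \cap Y|}{|X \cup Y|},$$

and HD95 is the 95th percentile (linear interpolation) of the pooled
directed boundary-to-boundary Euclidean distances in both directions — the
outlier-robust variant of the Hausdorff distance, symmetric by
construction. Conventions the definitions leave open:

* **Boundary set**: mask pixels with at least one 4-neighbour (or the image
  border) outside the mask.
* **Distances**: an exact two-pass squared Euclidean distance transform
  (parabola lower envelope), verified in the tests against an all-pairs
  $O(n^2)$ oracle.
* **Empty masks**: both empty → perfect agreement (DSC = IoU = 1,
  HD95 = 0); exactly one empty → DSC/IoU from the formulas (0), HD95
  undefined — `NA` by default, dropped from macro means, with a
  grid-diagonal worst-case penalty available. These conventions matter for
  per-class evaluation when a class is absent from a slice.
* **Pixel spacing** is fixed at 1 (distances in pixels); a spacing argument
  exists for future volumetric use.

`evaluate_masks()` reports one-vs-rest metrics per foreground class
(background excluded) plus unweighted macro averages.

## Synthetic data: what it emulates, what it does not

`fixture_spec()` defaults define the stated desk-scale world: 64×64 images,
4 classes (background + 3 "organs"), 3 rotated ellipses of varying size
(axes 8–28 % of the extent, uniform positions in the central 60 %), later
shapes overwriting earlier ones, intensity $(\mathrm{label} + 0.5)/K$ plus
Gaussian noise of SD 0.05 on a [0, 1] scale, replicated to three channels.
Every sample is a pure function of `(seed, index)`, so datasets are
reproducible without storing files.

The generator reproduces the *structural* features the pipeline needs —
multi-class label maps, class-dependent intensities, varying organ sizes,
touching/overlapping regions — but not the hard parts of real modalities:
no texture, no partial-volume boundaries, no intensity overlap between
classes, no anatomy. A green learnability test therefore establishes that
the architecture, gradients, optimiser and metrics interoperate and that
the model can fit a signal it is expressive enough for; it says nothing
about benchmark accuracy on real CT/MRI, which is out of scope here.

Augmentation uses flips and right-angle rotations only: 90° multiples keep
integer masks interpolation-free, so augmented pairs stay label-exact.

## Training

The loss is the field's standard compound for these benchmarks,
$0.5\,\mathrm{CE} + 0.5\,(1 - \overline{\mathrm{Dice}}_{\mathrm{soft}})$,
with the soft Dice averaged over all classes including background; weights
are configurable. Optimisation is AdamW at the published settings
(lr 2e-4, weight decay 1e-4, batch 8), no schedule by default, cosine decay
behind a flag.

Two scale-dependent choices are deliberate:

* The **reduced desk-scale runs** (0.75 M parameters, ≤300 steps) use
  lr 2e-3. The published 2e-4 belongs to a 40 M-parameter model trained for
  many epochs; a model 50× smaller on a 300-step budget needs a
  correspondingly larger step size. This was fixed once, on scaling
  grounds; `train_config()`'s default remains 2e-4.
* Learnability tests disable augmentation (they measure train-set fit, not
  generalisation).

## Numerical choices

* **No implicit padding**: partition operators reject extents not divisible
  by $P$/$G$ with an explicit error, keeping Block/Unblock exact inverses
  and tests deterministic. `model_config()` validates the whole
  divisibility chain at build time.
* **Initialisation**: truncated normal (σ = 0.02) for attention/linear
  maps, He-normal for convolutions, zeros for biases and relative-bias
  tables (so zero-query attention is exactly uniform at init), BatchNorm
  γ = 1. Initialisation draws from the session RNG; seed before
  `build_model()` for bit-reproducibility.
* **BatchNorm** uses biased batch variance, momentum 0.1 running buffers;
  deterministic tests run in inference mode with frozen statistics.
* **GELU** is exact, $x\,\Phi(x)$.
* **Autodiff**: the package carries its own reverse-mode tape on dense
  arrays (no deep-learning framework exists for this R stack). Every
  primitive's adjoint is hand-derived and checked against central finite
  differences in the test suite; a whole-model audit verifies that a single
  backward pass reaches every trainable parameter.
* **Soft-dice smoothing** uses ε = 1e-6 in numerator and denominator.
* **Checkpoints** embed a configuration digest; loading verifies it.

## Known limitations

* CPU-only and interpreter-bound: a training step on the reduced model
  costs seconds, so the package is a desk-scale research artifact, not a
  training system for the full 224² model.
* 2D only; volumes enter as axial slices (`read_nifti_slices()`), and HD95
  is computed per slice with unit spacing.
* BatchNorm statistics are per-process; there is no multi-device training.
* The NIfTI codec is deliberately minimal (little-endian NIfTI-1, common
  datatypes, no extensions); it is cross-checked against reference-library
  bytes in the tests but is not a general-purpose reader.
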