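---
title: "DEFIF-Net: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEFIF-Net: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`defifnet` implements a lightweight dual-encoder convolutional network for
binary segmentation of medical images — the regime where the target is
either one large irregular region (skin lesions in dermoscopic
photographs) or many small densely packed blobs (cell nuclei in
micrographs), and where deployment favours networks in the sub-million
parameter range.

The network is an asymmetric encoder–decoder:

* **Dual encoder.** Each of the L = 4 levels runs two streams on its
  inputs: a *local* stream of two 3×3 conv–BN–ReLU layers (the classical
  U-Net contracting block, receptive field a few pixels), and a
  *global-dependency* stream of one 7×7 conv–BN–ReLU layer, whose larger
  kernel captures longer-range spatial context at the same resolution.
  The two outputs are summed elementwise and refined by FIFConv (below).
  The refined map feeds the skip connection and, after 2×2 max pooling,
  the next global-dependency level; the local stream propagates its own
  pooled features. After level L the two pooled streams are merged by
  elementwise addition.
* **FIFConv** (feature interaction fusion convolution) on C channels:
  split into halves; lift each half to C channels with a 1×1 convolution;
  refine the first with a 2-group 3×3 convolution plus a parallel 1×1
  path, the second with an identity residual plus a 1×1 path; concatenate
  (2C channels); gate every channel by the sigmoid of its global average
  (a squeeze-style scalar gate, strictly inside (0, 1) for finite
  inputs); re-split into two C-channel halves and sum them. Output shape
  equals input shape.
* **CFRM** (channel feature reconstruction module) on each skip: split
  channels into halves; gate the first by
  `sigmoid(gap(x1) * w + b)` with `gap` the per-channel global average;
  pass the second through a grouped 3×3 convolution gated by
  `sigmoid(GroupNorm(x2) * w + b)`; concatenate and apply a 2-group
  channel shuffle. The learnable scales start at 0 and the shifts at 1,
  so a fresh module multiplies branch 1 by `sigmoid(1) ≈ 0.731`.
* **Bottleneck**: two 3×3 conv–BN–ReLU layers followed by the MBGM
  (multi-branch ghost module): a 3×3 entry convolution, a ghost-style
  primary 1×1 path P, a cheap secondary 1×1 path Q = conv1(P), an extra
  3×3 branch R = conv3(P), and a 3×3 exit convolution of `Q || (P + R)`.
  Every MBGM convolution carries BN + ReLU.
* **RFE decoder** (residual feature enhancement), per level: bilinear ×2
  upsampling, 1×1 channel adjustment, concatenation with the CFRM-processed
  skip, two 3×3 conv–BN–ReLU layers reducing to the level width (F1),
  FIFConv refinement (F2), and the residual sum F2 + F1.
* **Head**: 1×1 convolution; sigmoid for one class, per-pixel softmax
  otherwise.

Training minimises the weighted BCE–Dice objective

$$L = \alpha\left(1 - \frac{2\sum_i p_i g_i}{\sum_i p_i^2 + \sum_i g_i^2
+ \varepsilon}\right) + \beta\left(-\frac{1}{N}\sum_i [\,g_i \log p_i +
(1-g_i)\log(1-p_i)\,]\right)$$

with defaults α = 0.7, β = 0.3, ε = 10⁻⁶ (also used to clamp
probabilities before the logarithms). With α + β = 1 the loss is a convex
combination of its terms, which the tests exploit as an invariant.

## Where the design was genuinely open

Several structural details are not pinned by the architecture description;
the package fixes them as follows and treats them as part of its contract:

* **FIFConv channel widths.** As written, splitting C channels into halves
  and finishing with one elementwise sum of halves would return C/2
  channels, contradicting the stated C-channel output. The 1×1 lifts are
  therefore taken to map C/2 → C, the minimal reading under which the
  concatenation has 2C channels and the final sum restores C.
* **Gating granularity.** "Average pooling" before the FIFConv sigmoid is
  global spatial pooling — one scalar per channel — consistent with
  squeeze-style channel attention.
* **CFRM branch-2 operator** is a 3×3 grouped convolution (the more
  specific of the two descriptions available); group counts (convolution
  and group-norm) default to 2, falling back to 1 when C/2 is odd so that
  small widths remain valid.
* **Normalisation placement.** Only the MBGM specifies BN + ReLU per
  convolution. FIFConv and CFRM convolutions are therefore plain
  kernel + bias, exactly as their defining equations state. The encoder /
  decoder 3×3 stacks and the 7×7 convolutions use conv–BN–ReLU, the
  standard U-Net unit; the decoder 1×1 adjustment and the head are plain.
* **Downsampling / upsampling**: 2×2 max pooling (the explicitly
  parameterised operator) and parameter-free bilinear ×2 upsampling
  without corner alignment.
* **Stream topology**: the two encoder streams stay separate level to
  level (the fused map feeds only the global-dependency stream and the
  skip), and both the per-level fusion and the final stream merge are
  elementwise additions.
* **Decoder merge**: channel concatenation before the 3×3 reduction, and
  the residual source is the post-convolution map F1 — the only choice
  consistent with channel arithmetic.
* **Weight initialisation**: Kaiming fan-in draws from a seeded RNG; only
  CFRM's zero/one scale–shift initialisation is architecturally pinned.

## The channel schedule and the compute budget

Per-level channel widths are not part of the architecture description.
`scripts/calibrate_channels.R` searches doubling schedules (base width
b ∈ {4, 6, 8, 12, 16}, bottleneck c_L or 2·c_L) against the published
budget of 0.24 M trainable parameters and 0.33 G multiply-accumulates for
one 3×256×256 forward pass. No candidate meets both budgets: the closest,
base 4 with bottleneck 32, gives **0.17 M parameters and 0.40 G MACs** and
is hard-coded as the default. Within this family the two budgets pull in
opposite directions (larger bottlenecks add parameters faster than MACs;
wider early levels add MACs faster than parameters), so the published pair
appears to correspond to a non-doubling schedule, a different resolution,
or a different counting convention; the package reports its own honestly
computed numbers instead. The MAC convention is
`k² · C_in/groups · C_out · H_out · W_out` per convolution plus one
operation per output element for elementwise, pooling, resampling and
normalisation stages, profiled from an actual forward pass rather than a
separate formula, so the counter and the network cannot drift apart.

## Synthetic data: what it emulates and what it does not

The fixture generators make every training and evaluation path runnable
without downloads:

* **Lesion mode** draws a star-convex mask from a randomised radial
  function `r(θ) = r₀(1 + Σₖ aₖ sin(kθ + φₖ))` (amplitude halved and
  redrawn if the boundary would degenerate), composites a darker textured
  fill over a skin-tone background, blurs, adds Gaussian pixel noise and,
  with probability 0.3, dark hair strokes. Default mean radius fraction
  0.28 of the short side keeps foreground fractions within (0.05, 0.6);
  masks are single connected components by construction.
* **Nuclei mode** places 5–15 bright ellipses (radius 3–8 px) on a dark
  field by rejection sampling with a minimum separation, so component
  counts are controlled.
* Both are bit-reproducible given `(seed, index)`, and datasets written to
  disk round-trip losslessly through the PNG loader.

These fixtures reproduce the *geometry* of the two regimes (one large
irregular region vs. many small blobs) and the nuisance factors the
augmentation targets (hair occlusion, intensity noise), but not the
photometric statistics of real dermoscopy or microscopy — colour
constancy, vignetting, stain variation, ruler markers, out-of-focus
regions. Passing the synthetic learning check therefore demonstrates that
the architecture, gradients and training loop work end to end, not that
benchmark-level accuracy transfers to real datasets.

## Training protocol and numerical choices

Defaults follow the published protocol: Adam (the conventional choice;
the optimiser itself was unspecified), initial learning rate 10⁻⁴, decay
factor 0.5 on a validation-loss plateau with patience 10, batch size 8,
200 epochs, model selection by best validation DSC. The augmentation
suite is random rotation (reflected-border fill for images, zero fill for
masks, nearest-neighbour mask resampling), flips, crops resized back to
the input resolution, and synthetic hair strokes drawn as quadratic
Bézier polylines 1–3 px thick (the hair model is this package's own
parameterisation; the protocol only names "body-hair noise").

The *overfit harness* — the capability check that the default network can
drive training DSC ≥ 0.90 on 16 synthetic 64×64 lesions within 300
full-batch epochs — uses Adam at 10⁻³, the conventional full-batch step;
with a batch of 16 the 10⁻⁴ mini-batch rate is needlessly conservative.
In practice the target is reached in well under 50 epochs.

Other numerical choices: batch norm uses ε = 10⁻⁵ and momentum 0.1
(biased variance for normalisation, unbiased for the running estimate);
group norm uses ε = 10⁻⁵ without affine terms (the CFRM's learnable
scale–shift plays that role); probability maps are thresholded at 0.5
with a ≥ tie-break; 8-bit masks binarise at >127; empty-vs-empty masks
score 1 on all ratio metrics; the average Hausdorff distance is undefined
when exactly one mask is empty and returns `NA` with a warning. Problem
sizes in the test-suite were chosen so the whole suite and the learning
check run in a few minutes on one CPU core: oracle comparisons use 3–6 px
feature maps, end-to-end contracts run at 64–256 px, and the learning
check uses 16 images at 64×64.

## Gradient engine

There is no deep-learning framework dependency: the forward pass is built
on a compact reverse-mode differentiation tape whose convolution, pooling
and resampling kernels are compiled (im2col + BLAS matrix products). The
tape's gradients — including batch/group normalisation in training mode
and the loss terms — are validated against central finite differences in
the test-suite, at the primitive level and through the whole network.

## Known limitations

* Single-node CPU training only; practical for the package's synthetic
  regime and small studies, not for 200-epoch runs on full benchmark
  datasets.
* The multi-class head (softmax) is wired and shape-tested, but the
  combined loss and metrics target the binary case.
* Only PNG rasters are read.
* The average Hausdorff implementation is exact brute force, quadratic in
  foreground size — fine at the package's resolutions, slow for
  megapixel masks.
* The default channel schedule cannot reproduce the published
  parameter/MAC pair, as discussed above.

## Reproducing the numbers

```r
library(defifnet)
net <- build_network(model_config())
network_summary(net)      # parameters and MACs with per-stage breakdown
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the two budget figures from a fresh network, and
`scripts/calibrate_channels.R` prints the full calibration table behind
the default schedule.
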