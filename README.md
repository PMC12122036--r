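# defifnet

Binary segmentation of medical images with **DEFIF-Net**, a lightweight
dual-encoding feature interaction fusion network. The package targets the
two classic regimes of this task — one large irregular region (skin
lesions in dermoscopic photographs) and many small densely packed blobs
(cell nuclei in micrographs) — with a network small enough
(~0.2 M parameters) to train and run on a single CPU core.

## The model

DEFIF-Net is an asymmetric encoder–decoder. Each of the four encoder
levels runs a *local* stream (two 3×3 conv–BN–ReLU layers) alongside a
*global-dependency* stream (one 7×7 conv–BN–ReLU layer); their sum is
refined by the **feature interaction fusion convolution (FIFConv)**, a
split → lift → (grouped 3×3 + 1×1 / residual + 1×1) → concatenate →
sigmoid-gate → re-split → sum operator that mixes near and far feature
dependencies while keeping the channel count. Skip connections pass
through **channel feature reconstruction modules (CFRM)** — a globally
pooled gated half and a group-normalised grouped-convolution half,
re-interleaved by a 2-group channel shuffle. The bottleneck stacks two
3×3 convolutions and a **multi-branch ghost module (MBGM)**; decoding
uses **residual feature enhancement (RFE)** levels (upsample → 1×1 →
concat skip → two 3×3 → FIFConv → residual sum) and a 1×1 sigmoid head.

Training minimises the weighted BCE–Dice loss

    L = α · (1 − 2Σ pᵢgᵢ / (Σ pᵢ² + Σ gᵢ² + ε))
      + β · (−1/N Σ [gᵢ log pᵢ + (1−gᵢ) log(1−pᵢ)]),   α = 0.7, β = 0.3

Evaluation reports IoU, DSC, accuracy, recall and the symmetric average
Hausdorff distance (pixels). There is no deep-learning framework
dependency: the forward/backward passes run on a compact reverse-mode
autodiff tape with compiled (RcppArmadillo) convolution kernels, and the
gradients are finite-difference-checked in the test-suite.

## Worked example

Train on synthetic lesion fixtures (no downloads needed) and evaluate on
held-out samples:

```r
library(defifnet)

net <- build_network(model_config(input_size = c(64L, 64L), seed = 7L))
net
#> DEFIF-Net: depth 4 channels [ 4, 8, 16, 32 ] bottleneck 32
#>   input 64x64 x 3  classes 1
#>   trainable parameters: 171989

spec  <- synthetic_spec("lesion", image_size = c(64L, 64L), count = 20L, seed = 7L)
pairs <- generate_pairs(spec)
fit <- fit_network(net, pairs[1:16], pairs[17:20], epochs = 40L,
                   batch_size = 16L, lr = 1e-3, seed = 7L)
tail(fit$history, 3)[, c("epoch", "train_loss", "train_dsc", "val_dsc")]
#>  epoch train_loss train_dsc   val_dsc
#>     38 0.07677816 0.9697468 0.9447488
#>     39 0.07454741 0.9711521 0.9469195
#>     40 0.07242498 0.9724415 0.9498070

evaluate_network(net, pairs[17:20])
#> Segmentation metrics over 4 image(s):
#>   iou            0.9056 ± 0.0545
#>   dsc            0.9498 ± 0.0305
#>   acc            0.9733 ± 0.0140
#>   rec            0.9409 ± 0.0556
#>   avg_hausdorff  0.0688 ± 0.0524
```

After 40 epochs the network reaches a validation DSC of ~0.95 on held-out
synthetic lesions; the average Hausdorff distance of ~0.07 px says the
predicted and reference boundaries essentially coincide on this easy
synthetic geometry (see the methods vignette for what the fixtures do and
do not emulate).

Model size and compute:

```r
network_summary(build_network(model_config()))
#> Trainable parameters: 171989 (0.17 M)
#> MACs at 256x256: 396403018 (0.40 G)
#> ...per-stage breakdown...
```

## Command line

A thin launcher is installed at `inst/cli/defifnet` with verbs `synth`,
`train`, `eval`, `predict` and `summary` over a YAML run configuration,
e.g.

```sh
Rscript inst/cli/defifnet summary --config run.yaml
Rscript inst/cli/defifnet train   --config run.yaml
Rscript inst/cli/defifnet predict --checkpoint out/checkpoint.rds --images data/images --out out/masks
```

Defaults follow the published protocol: 200 epochs, batch size 8, Adam at
1e-4, decay factor 0.5 on plateau, α/β = 0.7/0.3, 7:2:1 split.

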