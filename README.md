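# acunet

An R implementation of a 2D **attention-gated convolutional U-Net** for
brain-tumor segmentation on multi-modal MRI, for researchers who want a
fully inspectable, dependency-light segmentation stack: the network, its
attention modules, the objective, the optimizer and every evaluation metric
are implemented in the package (R with small C++ convolution kernels) and
verified against independent oracles — no deep-learning framework required.

## What it implements

The model is a U-Net encoder-decoder over axial slices of four-channel
volumes (FLAIR/T1/T1CE/T2 by convention), extended with:

* **dual attention** at every level — a spatial branch
  (channel max/avg pool → conv → sigmoid) and a channel branch
  (global average pool → bottleneck MLP → sigmoid) run in parallel and are
  fused — and
* **attention-gated skip connections**, either
  `α = σ(Wᵀ[C, U] + b)` on the channel concatenation of encoder feature `C`
  and decoder feature `U` (default), or scaled dot-product attention
  `softmax(QKᵀ/√d)` with `Q = W_q U`, `K = W_k C` over spatial positions.

Training minimizes the weighted compound objective

```
L = λ_Dice · L_Dice + λ_CE · L_CE,   L_Dice = 1 − 2ΣPG / (ΣP + ΣG + ε)
```

by seeded mini-batch SGD (`θ ← θ − η ∇L`, optional momentum). Evaluation
follows the BraTS protocol over the nested regions WT (labels {1,2,4}),
TC ({1,4}) and ET ({4}): Dice, Jaccard, sensitivity, specificity, precision,
F1, and the surface distances HD95 and ASSD in mm. An ablation harness
trains the variant ladder (baseline U-Net, +channel, +spatial, decoder-only
dual attention, full model) under identical conditions, and k-fold
cross-validation reports fold-averaged metrics.

Because real BraTS data cannot be bundled, the package ships a seeded
multi-modal **phantom generator** (nested elliptical tumor subregions,
modality-like contrast, bias field, Gaussian noise) so the entire pipeline
— IO, training, evaluation, ablation — runs end to end in minutes with no
download.

## Worked example

```r
library(acunet)

# 1. a seeded synthetic dataset: 120 four-channel 64x64 slices
spec <- phantom_spec(n_samples = 120, shape = c(64, 64), seed = 42)
phantoms <- generate_phantoms(spec)
phantoms[[1]]
#> sample2d phantom_001[1]: 64 x 64 px, 4 channel(s), 601 tumor px

# 2. fit a small attention U-Net
fit <- acunet_train(phantoms,
                    model = model_config(depth = 3, base_width = 8,
                                         variant = "full", seed = 1),
                    train = train_config(epochs = 8, seed = 1))
fit
#> Fitted attention U-Net
#> acunet model config: variant 'full', gate 'concat_sigmoid'
#>   4 -> [8, 16, 32] -> 4 classes, depth 3, r = 8, spatial kernel 7x7, seed 1
#>   epochs run: 8 (best epoch 8, mean val dice 0.9364)

# 3. segment a held-out phantom and score it region-wise
test_sample <- generate_phantom(spec, seed = 999)
pred <- predict(fit, test_sample)[[1]]
evaluate_regions(pred, test_sample$mask)
#> Region-wise segmentation metrics
#>           dice jaccard sensitivity specificity precision     f1 hd95_mm assd_mm
#> WT      0.9492  0.9034      0.9971      0.9904    0.9058 0.9492       1  0.5966
#> TC      0.9852  0.9708      1.0000      0.9987    0.9708 0.9852       1  0.1250
#> ET      0.8966  0.8125      0.8125      1.0000    1.0000 0.8966       1  0.3548
#> Average 0.9437  0.8956      0.9365      0.9964    0.9588 0.9437       1  0.3588
```

The rows are the nested tumor regions; `dice` is the overlap with the
ground-truth region, `hd95_mm`/`assd_mm` are boundary distances in mm
(lower is better). `plot(fit)` draws the loss and validation-dice curves,
and `run_ablation(phantoms, c("baseline", "full"))` reproduces the
attention-vs-baseline comparison on the same split.

A command-line interface wraps the same functions
(`inst/cli/acunet make-phantoms | train | predict | evaluate | crossval |
ablate`), reading/writing NIfTI volumes, JSON manifests and CSV reports;
every command is rerunnable — identical seeds give byte-identical outputs.

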