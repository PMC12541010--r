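---
title: "Attention-gated U-Net segmentation: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated U-Net segmentation: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acunet)
```

## The segmentation problem

Gliomas appear on multi-modal MRI as nested regions with different contrast
signatures per pulse sequence: edema is bright on FLAIR and T2, the enhancing
rim lights up on post-contrast T1 (T1CE), and the necrotic core is
hypointense on T1. The BraTS labelling convention encodes this as integer
labels 1 (necrotic/non-enhancing core), 2 (edema) and 4 (enhancing tumor),
evaluated over three nested regions: whole tumor WT = {1, 2, 4}, tumor core
TC = {1, 4} and enhancing tumor ET = {4}. `acunet` implements a 2D
encoder-decoder network that segments individual axial slices of
four-channel volumes into these classes, plus everything needed to train and
evaluate it reproducibly.

## The network

The backbone is a standard U-Net ladder: at each of `depth` levels two
3×3 convolution + ReLU pairs, with 2×2 max-pooling between encoder levels
and channel widths doubling per level; the decoder mirrors the encoder with
learnable 2×2 stride-2 transposed convolutions, concatenating same-level
encoder features across skip connections; a 1×1 convolution and per-pixel
softmax over the four classes close the network. The kernel counts and
widths are the canonical U-Net choices; the defaults here
(`depth = 3`, `base_width = 8`) are sized so the phantom task below trains
in minutes on one CPU core.

Three attention mechanisms refine this backbone:

* **Spatial attention** pools each feature map across channels (max and
  mean), convolves the 2-channel result with a `spatial_kernel` ×
  `spatial_kernel` kernel (default 7) and applies a sigmoid, yielding a
  per-position weight in (0, 1) that multiplies every channel.
* **Channel attention** global-average-pools each channel, passes the
  length-`C` descriptor through a bottleneck MLP (`C → C/r → C`, ReLU then
  sigmoid, default reduction `r = 8`) and rescales channels by the result.
* **Attention gates** modulate encoder features before they cross a skip
  connection. Two formulations are provided. The default
  (`concat_sigmoid`) computes a per-position coefficient
  `α = σ(W'[C, U] + b)` by a 1×1 convolution over the channel concatenation
  of the encoder feature `C` and the upsampled decoder feature `U`, and
  returns `α · C`. The alternative (`qkv_softmax`) projects `U` to queries
  and `C` to keys over flattened spatial positions and reweights `C`'s
  positions by `softmax(QKᵀ/√d)`.

The *dual attention* module runs the spatial and channel branches in
parallel on the same feature map and fuses them; since the literature this
design follows states the branches are parallel but leaves the fusion
operator open, we fuse by the elementwise mean of the two refined maps
followed by a learnable 1×1 convolution — the cheapest operator that lets
training re-weight the two branches.

The `variant` field of `model_config()` reproduces an ablation ladder:
`baseline` (no attention), `channel_only` / `spatial_only` (that branch at
every encoder and decoder level), `decoder_only` (dual attention on decoder
features only) and `full` (dual attention at every level plus gated skips).
Because the two gate formulations appear side by side in the source
architecture without a stated choice, both are kept behind `gate_mode`;
`concat_sigmoid` is the default because its per-position coefficient
composes directly with the gating product `α · C`.

Two resolution details are fixed by fiat because the source architecture
leaves them open: decoder features reach the gate through the transposed
convolution, so encoder and decoder features are always compared at the
encoder's resolution; and the quadratic-memory `qkv_softmax` gate is applied
only at levels with at most 1024 spatial positions (32×32), falling back to
the concat gate at finer levels, which bounds the `n²` attention cost.

Weight initialization is He-normal, seeded by `model_config(seed = )`; two
builds from the same config are bit-identical.

## Objective and optimization

Training minimizes a weighted sum of a soft Dice loss and cross-entropy,

$$L = \lambda_{Dice} L_{Dice} + \lambda_{CE} L_{CE},
\qquad L_{Dice} = 1 - \frac{2\sum_i P_i G_i}{\sum_i P_i + \sum_i G_i + \varepsilon},$$

with defaults $\lambda_{Dice} = \lambda_{CE} = 0.5$ (no values are stated in
the source; equal weighting is the neutral choice, and both are exposed in
`loss_weights()`). The binary primitives `dice_loss()` and
`cross_entropy_loss()` implement the printed formulas — cross-entropy as a
sum, with a mean reduction offered because the mean keeps learning rates
comparable across image sizes; the multi-class training objective averages
the per-class soft Dice over the four classes and uses the mean categorical
cross-entropy. The smoothing constant $\varepsilon = 10^{-6}$ guards the
empty-empty denominator and is negligible against any nonempty mask.

Optimization is plain SGD, $\theta_{t+1} = \theta_t - \eta \nabla_\theta L$,
with an optional momentum buffer (default 0.9), $\eta = 0.05$ and batch
size 8. These are phantom-scale defaults: the task below is nearly linearly
separable per pixel, so a short schedule (10 epochs over 160 slices)
suffices; all values are configurable and recorded in run outputs. The
backward pass is hand-derived per module and verified against central
finite differences (relative error below $10^{-4}$ in the test suite; in
practice around $10^{-7}$).

Failure handling is deliberate: a non-finite loss aborts with a diagnostic
rather than skipping the batch, so divergence surfaces deterministically.
Checkpoint selection keeps the epoch with the best mean validation region
dice; when no validation set is supplied, a seeded 20% split is held out.

## Evaluation metrics

All reports are per region (WT/TC/ET after `derive_regions()`), with an
`Average` row of arithmetic means:

* Overlap: Dice `2tp/(2tp+fp+fn)`, Jaccard, precision, recall/sensitivity,
  specificity, F1. For binary masks F1 ≡ Dice and `J = D/(2−D)`; both
  identities are asserted in tests.
* Surface distances: boundary pixels are foreground pixels with a
  background 4-neighbour (image borders count as background); directed
  nearest-boundary distances are Euclidean, scaled by the pixel spacing in
  mm. HD95 is the max of the two directed 95th percentiles (linear
  interpolation, R's `type = 7`); ASSD is the symmetric mean. These
  conventions are pinned because published variants differ.
* Degenerate cases: both masks empty ⇒ overlap ratios 1 and distances 0
  (perfect agreement); prediction empty against a nonempty reference ⇒
  overlap 0 and distances flagged undefined (`NA` with attribute), excluded
  from averages with the count recorded — matching common BraTS evaluation
  practice. The source is silent here, so every convention is unit-tested
  explicitly.

## The phantom generator

`phantom_spec()` emulates what the pipeline needs from BraTS-style data
without any download: four co-registered channels over a smooth sinusoidal
bias field with additive Gaussian noise, and three concentric random
ellipses (random center, semi-axes, rotation; shrink factors drawn from
`tc_fraction_range` and `et_fraction_range`) writing labels 2/1/4 for the
nested subregions. The default contrast table makes channel 1 bright across
the whole tumor (FLAIR-like) — so WT is approximately recoverable by a
threshold on one channel, guaranteeing a small network can learn the task
quickly — and channel 3 bright in the enhancing core (T1CE-like), with the
edema/core/enhancing signatures separated by several noise standard
deviations (noise sd 0.05 against offsets of 0.2-0.9).

Default geometry: 64×64 px slices, whole-tumor semi-axes 8-16 px, tumor in
every sample. The expected WT area fraction is then
$\pi \mathbb{E}[a]\,\mathbb{E}[b] / (HW) \approx 0.11$, which the test suite
checks against the empirical mean within three standard errors.

What the phantoms do **not** emulate: Rician noise statistics, partial
volume effects, bias-field inhomogeneity beyond a single smooth harmonic,
non-elliptical tumor topology, inter-slice context, or class imbalance as
extreme as clinical data. Passing the phantom-scale tests therefore
demonstrates that the architecture, objective, optimizer and metrics are
implemented correctly and can fit a learnable segmentation task — not that
the default hyperparameters transfer to clinical MRI.

## Experiment harnesses

`kfold_split()` partitions indices by a seeded permutation into folds whose
sizes differ by at most one; `cross_validate()` trains one model per fold
and reports the arithmetic fold mean. `run_ablation()` trains each
requested variant under identical conditions — the same seed, the same
held-out comparison split, the same loss and preprocessing — and tabulates
held-out WT/TC/ET dice per variant. End-to-end determinism (dataset seed,
model seed, train seed fully determine every reported number, byte-for-byte
in the CSV outputs) is an explicit test target.

The problem sizes used by the acceptance checks — 200 phantoms at 64×64,
a depth-3/width-8 model, 10 epochs — were chosen as the smallest
configuration at which the full variant comfortably saturates the phantom
task; on one CPU core a training run takes a few minutes.

## Known limitations

* 2D slice-wise only; no 3D convolutions (the natural extension).
* The qkv gate's quadratic cost restricts it to coarse levels; no windowed
  or sparse attention is provided.
* No learning-rate schedules or adaptive optimizers; plain SGD with
  momentum is sufficient at phantom scale and keeps runs exactly
  reproducible.
* The CLI reads/writes NIfTI-1 only; DICOM ingestion, bias-field
  correction, skull stripping and registration are out of scope.
* ROC/AUC threshold sweeps are not drawn; per-class probability volumes are
  exported so external tools can compute them.
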