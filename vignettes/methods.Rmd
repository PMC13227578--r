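---
title: "Methods: a dual-head Vision Transformer for speckled ultrasound-style images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dual-head Vision Transformer for speckled ultrasound-style images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalvit)
```

## The model

`fetalvit` implements a patch-based Vision Transformer over grayscale
images with two output heads trained jointly:

* a **classification head** producing softmax probabilities over health
  classes, `softmax(W_class f + b_class)`;
* a **severity head** producing a continuous abnormality score as the
  affine map `w_severity . f + b_severity`.

The shared trunk is standard: an `H x W` image is cut into non-overlapping
`P x P` patches (`P` must divide both dimensions; there is no implicit
padding), each flattened row-major and mapped by one learnable linear layer
into `D`-dimensional tokens. Fixed sinusoidal positional encodings are
added (`sin`/`cos` pairs over the row-major patch index; an optional
factored 2-D variant encodes patch row and column in separate channel
halves). The token sequence then passes through `depth` pre-norm encoder
blocks — multi-head scaled dot-product self-attention
`softmax(Q K' / sqrt(d_k)) V` followed by a ReLU feed-forward of width
`mlp_mult * D`, each with a residual connection — optionally one
cross-attention block whose queries come from the final layer and whose
keys/values come from an earlier layer, and finally mean pooling over
tokens. There is no CLS token; the pooled mean feeds both heads, so the
pooled feature dimension equals `D`.

Training minimizes the composite loss

```
L_total = L_class + lambda * L_severity
```

with `L_class` the cross-entropy of the predicted class distribution and
`L_severity` the mean squared error of the severity score. Optimization is
mini-batch Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) with
*decoupled* weight decay (`theta <- theta - eta0 * gamma * theta` applied
after the Adam step). Early stopping monitors the validation `L_total` and
halts after `patience` epochs without an improvement larger than
`min_delta`; the parameters from the best-validation epoch are returned.
The forward and backward passes are written directly in R as matrix
algebra; every gradient path (layer norm, multi-head attention,
cross-attention, the feed-forward, both heads, the patch embedding) is
verified against central finite differences in the test suite.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| image size | 224 x 224 | the conventional transformer input resolution; 256 x 256 also divides evenly by the default patch size |
| `patch_size` | 16 | 196 tokens at 224 x 224, the standard grid |
| `embed_dim` (D) | 64 | small enough to train on one CPU while keeping multi-head structure (4 heads x d_k 16) |
| `depth` / `heads` | 4 / 4 | unstated in the source method; chosen as the smallest stack that retains multi-layer rollout structure |
| `n_classes` | 3 | matches the reference classification report; 4 (healthy/mild/moderate/severe) is fully supported via `n_classes = 4` |
| `lambda` | 0.5 | the balanced setting of the composite loss |
| `learning_rate` / `weight_decay` | 1e-3 / 1e-4 | mid-range of the swept rates; decay small enough not to dominate early training |
| `batch_size` | 16 | keeps per-step latency low at CPU scale |
| `patience` / `min_delta` | 5 / 1e-4 | a "set number of epochs" made concrete; 1e-4 absolute keeps noise from resetting the counter |
| heads = 1 | — | reproduces the single-head attention equations exactly (multi-head is parallel blocks concatenated, no output projection) |

Cross-attention is implemented (queries from the last encoder layer,
keys/values from a configurable earlier layer, default layer 1) but **off
by default**: whether it was active in the reference model is not stated,
and the plain encoder is the more conservative default. Enabling it is one
config flag.

Class count is a genuine ambiguity in the source material: the data are
described with four classes, the classification report uses three. Both
are supported; the default follows the report.

## Attention maps and their metrics

`extract_attention_map()` uses attention rollout: each layer's
head-averaged attention matrix gets an identity residual (`(A + I)/2`,
rows renormalized) and the layers are multiplied recursively; token
relevance is the column mean of the product (the mass each patch receives,
averaged over queries), upsampled nearest-neighbour to pixel resolution
and normalized to unit energy. A depth-0 trunk yields the uniform map by
construction.

The alignment metrics compare an attention map `A` against a binary
annotation `R` (0-based pixel-center coordinates; intensity-weighted
centroids for maps, uniform for masks):

* **CoG shift** — Euclidean distance between the centroids of `A` and `R`.
* **AFR** — binarize `A` at the top-10%-of-pixels-by-weight threshold
  (configurable quantile) and report `100 |A ∩ R| / |A|`.
* **WRS** — attention-weighted mean of `exp(-d^2 / (2 sigma^2))` with `d`
  the distance to the centroid of `R` and `sigma = sqrt(|R| / pi)` (the
  equivalent circle radius), so the best attainable score is exactly 1.
* **AED** — percentage of attention energy outside `R`; inside and outside
  shares sum to 100 exactly.
* **ODM** — mean per-frame IoU between the binarized map and its mask
  across a sequence (a frame-to-frame map-overlap reading is available
  behind a flag).
* **IoU/DSC** — standard overlap ratios; two empty masks return 100 by
  convention, and `DSC = 2 IoU / (100 + IoU) * 100` is verified
  exhaustively on all pairs of 3 x 3 masks.

The exact algebra of the thresholds and the WRS kernel is a package
decision — the source prints these metrics only as figures, so the prose
definitions were implemented and the free choices (quantile threshold,
Gaussian kernel with equivalent-radius bandwidth) are documented here
rather than claimed as reproductions.

## The phantom generator

Because the clinical dataset is private, `generate_phantom()` synthesizes
the study conditions: fan-shaped (60° sector) grayscale images of a smooth
tissue texture multiplied by Rayleigh-distributed speckle — the standard
first-order approximation of ultrasound speckle, with scale
`sqrt(2/pi)` so the speckle has unit mean — plus, for non-healthy classes,
1–3 hypoechoic elliptical lesions whose count, area and contrast increase
monotonically with the continuous severity score. Severity lives on
`[0, 3]` with class bands healthy `[0, 0.5)`, mild `[0.5, 1.5)`, moderate
`[1.5, 2.5)`, severe `[2.5, 3]`; the scale makes severity MAE values
commensurate with errors on the order of a few tenths. Masks mark lesion
pixels exactly, healthy phantoms have empty masks, and every draw is fully
determined by its seed (`generate_dataset()` derives per-image seeds from
one master seed and tags a stratified train/val/test split).

What the phantoms are **not**: a physical acoustics simulation. There is
no point-spread function, no depth-dependent attenuation, no anatomy.
Passing the training and attention tests on phantoms demonstrates that the
implementation learns and localizes a planted, well-separated signal; it
says nothing about clinical performance on real fetal ultrasound.

`plant_attention_target()` produces maps whose alignment metrics have
closed forms (weight `exp(sharpness)` on the mask, 1 elsewhere,
normalized), which is how the AFR/AED/WRS/CoG limits are tested without a
trained model in the loop.

## Statistical evaluation

The classification report computes per-class precision/recall/F1,
support-weighted and macro averages, accuracy and Cohen's kappa
`(p_o - p_e) / (1 - p_e)` with `p_e` from the marginal products. On the
10-sample reference confusion matrix the standard formula gives
kappa = 0.848; the reference table prints 0.83, which that matrix cannot
produce — the package reports the formula value and does not special-case
the table. Cohen's d defaults to the mean-of-SDs standardizer because that
convention reproduces the printed effect size (3.37) from the printed
means and SDs; the RMS-pooled form (3.33 on the same inputs) is one
argument away. Confidence intervals use the normal approximation
`mean ± z sd / sqrt(n)`. Report rounding follows the tables: two decimals
for rates and effect sizes, one for percent improvements.

## The lambda trade-off, as printed

The loss is implemented exactly as printed: `lambda` multiplies the
severity term only. A consequence worth stating plainly: **raising
`lambda` shifts training effort toward the severity task**, so severity
accuracy (defined for reporting as `100 (1 - MAE / range)`, a convention
the source leaves undefined) tends up and classification accuracy tends
down — the opposite direction to the reference trade-off table, whose
stated trend (higher λ favouring classification) is only consistent with
a loss in which λ weights the classification term instead. We follow the
printed formula, expose the sweep harness (`lambda_sweep()`) that
recomputes the table's percent-change columns exactly from its printed
accuracies, and leave the directional acceptance check red rather than
silently redefining λ. The corresponding test documents this conflict in
place.

## Problem sizes used by the tests

The suites train at reduced scale, chosen once: learnability uses 400
phantoms at 32 x 32 (patch 8, D = 32, depth 2, ≤ 20 epochs, 3 seeds);
direction properties (ablation, learning-rate, lambda) use 160 phantoms at
32 x 32 with depth 1 over 5 seeds; unit-level training checks use 40–60
phantoms at 16 x 16. These sizes keep each property a few minutes of CPU
while staying in the regime where the healthy-vs-severe signal is
comfortably learnable (≥ 90% validation accuracy).

## Numerical notes and edge cases

* Softmax rows are max-shifted before exponentiation; attention rows sum
  to 1 within 1e-9 and this is asserted in tests.
* Layer norm uses `eps = 1e-5` and no learnable affine terms.
* Cross-entropy clamps zero probabilities at 1e-12 instead of returning
  infinity (configurable).
* `normalize_image()` rejects constant images (zero range); `patchify()`
  rejects patch sizes that do not divide the image (no implicit padding).
* Bilinear resampling aligns corners (output pixel `i` samples input
  coordinate `i (H_in - 1) / (H_out - 1)`), uses reflect padding for
  rotation/zoom, and zero-fills shifts; resizing an image to its own shape
  is the identity. Interpolation cannot overshoot the input range.
* Augmentation draws the rotation angle uniformly from `[-theta, theta]`
  and the flip as Bernoulli(p) in training mode; the deterministic mode
  uses the fixed angle and flips iff `p >= 1`. All randomness is locally
  seeded (`.Random.seed` is saved and restored), so no package function
  perturbs the caller's RNG state.
* Checkpoints store plain numeric arrays plus a JSON config sidecar and
  round-trip bit-exactly.

## Known limitations

* Pure-R matrix algebra: fine at the tested scales (hundreds of images,
  tens of tokens), not meant for 224 x 224 training runs of many epochs.
* The phantom severity scale and the severity-accuracy reporting formula
  are package conventions, not clinical quantities.
* Attention rollout is one defensible saliency extraction among several;
  no claim is made that it matches the (unstated) extraction behind the
  reference attention tables.
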