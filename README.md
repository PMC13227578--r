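# fetalvit

A pure-R implementation of a **dual-head Vision Transformer** for grayscale
fetal-ultrasound-style images. One shared patch-transformer trunk feeds two
output heads at once:

* a **classification head** — softmax probabilities over fetal health
  classes, `Prob = softmax(W_class · f + b_class)`;
* a **severity head** — a continuous abnormality score as the affine map
  `s = w_severity · f + b_severity`.

Training minimizes the composite loss

```
L_total = L_class + λ · L_severity
```

(cross-entropy plus λ-weighted mean squared error) with mini-batch Adam,
decoupled weight decay and early stopping on the validation loss. The trunk
is the standard recipe: non-overlapping `P×P` patches, a learnable linear
patch embedding into `D` dimensions, fixed sinusoidal positional encodings,
pre-norm encoder blocks with multi-head self-attention
`softmax(QKᵀ/√d_k)·V` and a ReLU feed-forward, an optional cross-attention
block across layers, and mean pooling over tokens. Forward *and backward*
passes are plain R matrix algebra; all gradients are verified against
finite differences in the test suite.

Who this is for: anyone who wants a small, fully inspectable,
dependency-light reference implementation of multi-task ViT training and
attention-map evaluation that runs on one CPU — for teaching, for auditing
the arithmetic of the method, or as a harness for metric research. It is
not a GPU training framework.

Because clinical fetal ultrasound data are private, the package ships a
**speckle phantom generator**: fan-shaped images of smooth tissue texture
multiplied by Rayleigh speckle, with 1–3 hypoechoic elliptical lesions
whose number, size and contrast grow with a continuous severity score in
[0, 3] (class bands: healthy < 0.5 ≤ mild < 1.5 ≤ moderate < 2.5 ≤
severe), plus exact lesion masks. Every other component is exercised
end-to-end against these phantoms.

Also included:

* **attention-rollout saliency maps** and an alignment metric battery
  against annotation masks: centre-of-gravity (CoG) shift, attention focus
  ratio (AFR), weighted relevance score (WRS), attention energy
  distribution (AED), overlap dynamics metric (ODM), IoU and DSC;
* a **statistics suite**: classification report with Cohen's kappa,
  MAE/RMSE, residual density comparison, normal confidence intervals,
  Cohen's d (mean-of-SDs and pooled), percent change, and an
  original-vs-augmented A/B report;
* **harnesses** for ablation (positional encoding, self-attention, the
  second head), learning-rate sweeps (epochs to convergence) and λ sweeps
  (classification/severity accuracy trade-off);
* a **CLI** (`exec/fetalvit`) with subcommands `generate-data`,
  `preprocess`, `train`, `evaluate`, `attention-metrics`, `ablation`,
  `lr-sweep`, `lambda-sweep`, `worked-example`, `report`.

## Worked example

The dual heads on a pooled feature vector `x = (2.0, −1.5, 0.5)` with small
hand-checkable parameters:

```r
library(fetalvit)
worked_example()
#> Pooled transformer output x = [2, -1.5, 0.5]
#> Logits  W_class x + b_class = [ 0.75, -1.80,  1.70]
#> Class probabilities softmax = [0.273, 0.021, 0.706]
#> Severity  w . x + b        = 2.05
```

The model assigns 27.3% / 2.1% / 70.6% to the three health classes and a
severity score of 2.05.

## End-to-end on phantoms

```r
ds <- generate_dataset(n = 200,
        class_proportions = c(healthy = 0.5, mild = 0, moderate = 0, severe = 0.5),
        seed = 11, height = 32, width = 32)
samples <- as_model_samples(ds$samples, binary_severe = TRUE)
train <- samples[ds$manifest$split == "train"]
val   <- samples[ds$manifest$split %in% c("val", "test")]

cfg <- validate_config(list(image_height = 32, image_width = 32, patch_size = 8,
                            embed_dim = 32, depth = 2, heads = 4, n_classes = 2,
                            max_epochs = 15, seed = 1))
fit <- train_model(train, val, cfg)
fit
#> <vit_fit> 15 epochs (best 15): val accuracy 0.900, val MAE 0.669, val loss 0.5997

ev <- evaluate_model(fit$params, val, cfg)
classification_report(ev$y_true, ev$y_pred, 2)
#>  class precision recall  f1 support
#>      0      0.88   0.93 0.9      30
#>      1      0.93   0.87 0.9      30
#> accuracy 0.90 | weighted P/R/F1 0.90/0.90/0.90 | macro P 0.90 | kappa 0.80
```

The fitted model separates healthy from severe phantoms at 90% validation
accuracy in 15 epochs on one CPU (about half a minute). Attention maps and
their alignment with the lesion mask:

```r
vcfg <- fetalvit:::config_to_vit(cfg)
lesion <- which(vapply(val, function(s) any(s$mask), logical(1)))[1]
att <- extract_attention_map(fit$params, val[[lesion]]$image, vcfg)
round(attention_eval_report(att, val[[lesion]]$mask), 3)
#>   cog_shift  afr   wrs    aed    odm    iou    dsc
#> 1     2.189 37.5 0.285 81.829 13.483 13.483 23.762
```

CoG shift is in pixels (lower is better); AFR is the percentage of the
thresholded attention area inside the lesion; WRS ∈ (0, 1] rewards mass
near the lesion centroid; AED is the percentage of attention energy wasted
outside the lesion; ODM/IoU/DSC are overlap percentages. An untuned
depth-2 model localizes only loosely, as the numbers show — the metrics
are the point, not the saliency quality.

The same pipeline from the shell:

```sh
fetalvit generate-data --out data --n 200 --seed 11 --height 32 --width 32
fetalvit train --data-dir data --out run --config cfg.json
fetalvit evaluate --checkpoint run/checkpoint.rds --data-dir data --out eval
fetalvit worked-example
```

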