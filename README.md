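# stagevit

Ordinal severity grading of lesion images with a stage-aware vision
transformer, implemented entirely in R.

Screening endoscopy produces still images whose clinical reading is ordinal,
not binary: a lesion sits somewhere on the spectrum **Benign → Low-Risk →
High-Risk → Malignant**, and management follows its position on that
spectrum. `stagevit` implements a classifier built around this ordering:

* a **ViT encoder** — patch embedding with a [CLS] token and learnable
  positional encodings, pre-norm transformer blocks
  (`u ← u + MHSA(LN(u))`, `u ← u + FFN(LN(u))`, softmax attention
  `softmax(QKᵀ/√dₕ)V`, GELU feed-forward, dropout on attention weights and
  feed-forward outputs);
* a **Sequential Feature Learner (SFL)** that copies the [CLS] state to four
  stage positions, adds learned stage embeddings `sₖ = z + eₖ`, mixes them
  with two self-attention layers, re-projects each through a GELU
  feed-forward (768 → 1024 → 512 in the base geometry) and mean-pools;
* **dual heads** on the pooled vector: a 4-class softmax classifier and a
  sigmoid unit emitting a continuous malignancy risk score `r ∈ (0,1)`,
  trained jointly with the weighted loss
  `L = w_y · CE(p̂, y) + λ (r − y/3)²`;
* **Score-CAM attribution**: final-block token maps are normalized,
  upsampled, used to mask the input, and weighted by the change in target
  class score against a zero baseline; heatmaps are scored against
  ground-truth lesion masks by an overlap-concordance rule;
* the **evaluation suite**: support-weighted precision/recall/F1 (weighted
  recall ≡ accuracy), one-vs-rest and micro-averaged ROC AUC (midrank tie
  convention), risk-score monotonicity across classes, adjacent-error
  fraction, and an ablation harness (`full`, `no_progression`,
  `no_self_attention`) under matched training conditions.

Forward pass, analytic backpropagation and AdamW are hand-written in base R
matrix algebra — no deep-learning framework is required — and a synthetic
ordinal lesion generator (star-convex blobs with class-increasing area,
border irregularity, texture contrast and vascular-pattern density, plus
paired masks) makes the whole pipeline runnable and testable at desk scale.

## Worked example

```r
library(stagevit)

# 1. synthesize a balanced ordinal dataset (240 images, 4 classes) and split it
params <- severity_params(n_per_class = 60, seed = 42)
ds <- generate_dataset(params)
manifest <- stratified_split(ds$manifest, fractions = c(4, 1, 1) / 6, seed = 42)
records <- apply_split(ds$records, manifest)
train <- Filter(function(r) r$split == "train", records)
val   <- Filter(function(r) r$split == "val", records)
test  <- Filter(function(r) r$split == "test", records)

# 2. train the tiny stage-aware ViT (64 px, width 64, 2 blocks)
fit <- train_model(model_config("tiny"),
                   train_config(lr = 5e-4, max_epochs = 20, patience = 5),
                   train, val, seed = 0)

# 3. evaluate the full metric suite on the held-out split
report <- evaluate_model(fit$model, test)
print(report)
```

```
accuracy 0.7750  precision_w 0.7653  recall_w 0.7750  f1_w 0.7518
micro AUC 0.9733  per-class AUC 1.000 0.983 0.910 0.977
risk means 0.046 0.572 0.733 0.837  monotone TRUE
adjacent-error fraction 1.000 (9 errors)
```

Reading this: even after a deliberately short run (160 training images, 20
epochs) the categorical head classifies the 40 held-out images at 77.5%
accuracy with strong one-vs-rest discrimination; the continuous risk score
rises strictly with the true ordinal class (class means 0.05 → 0.57 → 0.73
→ 0.84), which is the behavior the SFL is built to encourage; and every one
of the nine residual errors is between adjacent grades — the clinically
benign error mode. The larger run performed by `scripts/acceptance.R`
(below; 400 training images, up to 30 epochs) reaches ≥ 0.9 accuracy under
the same protocol.

```r
# 4. attribute one malignant test image and score it against its mask
lesion <- Filter(function(r) r$label == 3, test)[[1]]
img <- preprocess(lesion$pixels, 64)
hm <- score_cam(fit$model, img, top_k = 32)
overlap_concordance(hm, lesion$mask)[c("overlap_fraction", "concordant")]
```

```
$overlap_fraction
[1] 0.7043673

$concordant
[1] TRUE
```

Here 70% of the heatmap's high-activation region falls inside the annotated
lesion, so the attribution is concordant at the default thresholds. `overlay_heatmap(hm, img)` renders the usual color overlay.

A thin command-line front end over the same functions ships in
`inst/cli/stagevit.R` (subcommands `generate`, `split`, `train`, `evaluate`,
`explain`, `ablate`).

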