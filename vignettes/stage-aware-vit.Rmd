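---
title: "Ordinal severity grading with a stage-aware vision transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal severity grading with a stage-aware vision transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Endoscopic decision-making is rarely binary. Lesions of the gastrointestinal
tract occupy a spectrum from normal mucosa through non-dysplastic findings and
dysplasia to frank carcinoma, and management (surveillance interval, biopsy,
resection) tracks position on that spectrum rather than a detect/no-detect
verdict. `stagevit` implements an image classifier built around this ordinal
structure: given an RGB still image it emits

* a categorical prediction over four ordered risk strata
  (0 Benign, 1 Low-Risk, 2 High-Risk, 3 Malignant),
* a continuous *malignancy risk score* in $[0,1]$, interpreted as relative
  position on the learned severity spectrum (not a calibrated probability),
* and a gradient-free Score-CAM attribution heatmap that can be scored
  against an annotated lesion mask.

Everything — the transformer encoder, the progression-aware module, training,
and attribution — is implemented in base R matrix algebra with analytic
backpropagation, so the whole pipeline runs and is testable at desk scale
with no deep-learning framework.

## Model

### Encoder

An image resized to $S \times S$ and min–max normalized to $[0,1]$ is cut
into non-overlapping $P \times P$ patches in row-major order ($S/P = n$
per side, $n^2$ patches; the classical geometry is $224/16$, giving
$14 \times 14 = 196$ patches). Each flattened patch $x_i \in \mathbb{R}^{3P^2}$
is embedded as $t_i = W_e x_i + b_e + p_i$ with learnable positional
encodings $p_i$; a learnable classification token $t_0 = c + p_0$ is
prepended. The sequence passes through $L$ pre-norm transformer blocks

$$
u = u + \mathrm{MHSA}(\mathrm{LN}(u)), \qquad
u = u + W_2\,\mathrm{GELU}(W_1 \mathrm{LN}(u) + b_1) + b_2,
$$

with $H$-head softmax attention $\mathrm{softmax}(QK^\top/\sqrt{d_h})V$,
dropout applied to the attention weights and to the feed-forward outputs,
and a final layer normalization after the last block (standard for pre-norm
stacks, which otherwise accumulate unnormalized residuals). The final
[CLS] state is the global lesion descriptor; the final patch-token states
feed the attribution module.

### Sequential feature learner (SFL)

The ordinal structure is modeled by evaluating the image representation
against all four severity stages at once. The [CLS] vector $z$ is copied to
four stage positions and combined **additively** with learned stage
embeddings, $s_k = z + e_k$, $k = 0, \dots, 3$. Two pre-norm residual
self-attention layers mix the four stage tokens, a per-token feed-forward
$D \to d_2 \to d_3$ with GELU after each linear map re-projects them
(768 → 1024 → 512 in the base geometry), and the four outputs are averaged
into the pooled vector that feeds both heads.

Additive combination was chosen over concatenation because it keeps the
stage-token width equal to the encoder width $D$, which is the input width
the published SFL feed-forward (768 → 1024) requires; concatenation along
the feature dimension would double it.

One structural property is worth stating explicitly: because the stage
embeddings are combined additively, self-attention is
permutation-equivariant, and the pooling is a mean, the pooled output is
*exactly invariant* to permuting the four stage embeddings. The module
learns four distinct reference directions (altering any one of them changes
the output — the test suite checks both facts), but the benign-to-malignant
*order* is induced by the training targets (the class labels and the ordinal
risk anchors), not by the SFL's wiring.

### Heads and loss

The pooled vector $v$ feeds two parallel heads: a linear 4-way classifier
with softmax, and a linear unit with sigmoid emitting the risk score
$r \in (0,1)$. The joint loss for an image with label $y$ is

$$
\mathcal{L} = w_y \,\mathrm{CE}(\hat p, y) + \lambda\,(r - y/3)^2 ,
$$

with inverse-frequency class weights $w$ normalized to mean 1 (all 1 for
balanced data) applied to the cross-entropy term only, since the regression
target already encodes the label. The regression anchors $y/3 \in \{0,
\tfrac13, \tfrac23, 1\}$ are the minimal equally spaced monotone encoding of
the four stages; $\lambda$ (default 0.5) trades classification accuracy
against risk-score calibration and is meant to be tuned on the validation
set (`tune_lambda()`). Internally the CE is computed from logits via
log-sum-exp; the probability-space API (`combined_loss()`) clamps
probabilities at $10^{-12}$ before the log.

### Ablation variants

`build_model()` exposes the two ablations used by the evaluation harness:
`no_progression` removes the SFL and attaches both heads directly to the
[CLS] embedding; `no_self_attention` keeps the SFL but replaces each
attention sublayer with a width-preserving fully connected layer with GELU
(pre-norm and residual unchanged).

## Training

Optimization follows the study protocol: AdamW (decoupled weight decay
$10^{-2}$ applied uniformly to all parameters), batch size 32, at most 50
epochs with early stopping on validation loss (patience 5), best-validation
checkpoint retained, class-weighted loss, both heads trained jointly from
the start, and repeated runs over three seeds with mean test metrics
(`multi_seed_run()`). Augmentation — horizontal/vertical flips, rotations up
to ±20°, translations up to 10%, brightness/contrast jitter in [0.8, 1.2] —
is applied on the fly to the training split only; rotation and translation
share one bilinear resampling pass with reflection padding so no dark
corners are introduced for the attribution maps to latch onto. All
randomness (initialization, shuffling, dropout, per-epoch per-image
augmentation streams) derives from the run seed, so training is exactly
reproducible.

Two numerical choices depart from common defaults and deserve a note:

* **Initialization.** Linear maps use a truncated normal with Glorot scale
  $\sigma = \sqrt{2/(\text{fan}_{in} + \text{fan}_{out})}$ (clipped at
  $2\sigma$); embeddings use the conventional $\sigma = 0.02$. A flat
  $\sigma = 0.02$ for all weights — the convention quoted for width-768
  transformers, where it coincides with the Glorot scale — starves narrow
  models: at width 64 the SFL's non-residual feed-forward emits activations
  at $\sim 5\cdot10^{-3}$ scale, and under AdamW weight decay the heads can
  never grow logits to order 1 within a desk-scale step budget. The model
  then stalls at the degenerate optimum that separates "lesion vs. no
  lesion" but leaves the three lesion grades at uniform probability.
  Fan-in-aware scaling removes the pathology while being the same
  initialization regime at base width.
* **Learning rate for the tiny preset.** The protocol rate $10^{-4}$ is a
  fine-tuning rate for a pretrained ViT-Base. The tiny preset trains from
  scratch; its desk-scale runs use $5\cdot10^{-4}$, selected on validation
  behavior (rates from $3\cdot10^{-5}$ to $10^{-3}$ were examined;
  $10^{-3}$ is unstable, below $10^{-4}$ convergence does not complete
  within 30 epochs).

## Synthetic ordinal data

No endoscopic images ship with the package. `severity_params()` /
`generate_dataset()` produce a desk-scale surrogate with the same *logical*
structure as a four-strata endoscopy dataset: balanced classes, paired
ground-truth lesion masks, and class-conditional morphology in which every
dial increases with severity —

| dial | class 0 | 1 | 2 | 3 | emulates |
|---|---|---|---|---|---|
| lesion area fraction | 0 | 0.05 | 0.12 | 0.22 | lesion size |
| border irregularity (radial sin amplitude) | 0 | 0.10 | 0.25 | 0.45 | irregular margins |
| texture contrast | 0 | 0.15 | 0.30 | 0.50 | mucosal texture change |
| vascular curves (random walks) | 0 | 2 | 4 | 6 | abnormal vascular pattern |

Lesions are star-convex blobs $r(\theta) = r_0 (1 + a \sum_{k=2}^{5} c_k
\sin(k\theta + \phi_k))$ with $\sum_k |c_k| = 1$, placed at a random
position on a smooth mucosa-like background (low-frequency color field plus
Gaussian noise, default sd 0.02); class 0 contains no lesion. The
`"overlapping"` preset narrows the gap between classes 1 and 2 (areas 0.09
vs. 0.13, irregularity 0.12 vs. 0.20, contrast 0.18 vs. 0.26, noise sd
0.04) so that separating the middle grades genuinely requires the ordinal
morphology cues; it is the condition under which the ablation harness
compares the full model against `no_progression`.

What the generator does **not** emulate: photorealistic mucosa, imaging
modalities (white light vs. narrow band), specular highlights, occlusion,
class imbalance, or intra-class heterogeneity of real lesion types. Passing
the test suite therefore demonstrates that the implementation recovers the
mechanisms it claims (ordinal separation, monotone risk scores, spatially
faithful attribution) on data where those mechanisms are the signal — it is
not evidence about performance on clinical images.

Splits are stratified: within each class, quotas `fraction × n` are rounded
by the largest-remainder rule (totals exact), and assignment is a seeded
within-class shuffle. 8000 balanced records at 80/10/10 give exactly
6400/800/800.

## Score-CAM

For a target class $t$, the final-block patch tokens are reshaped channel by
channel into $n \times n$ maps (row-major, matching patch order). Each of the
`top_k` maps with the largest spatial variance is min–max normalized,
bilinearly upsampled to input resolution, and multiplied elementwise into
the input image; the masked images and an all-zero baseline are re-forwarded
in one batch. Channel $c$'s weight is $w_c = p_t(\text{masked}_c) -
p_t(\mathbf{0})$, and the heatmap is $\max(0, \sum_c w_c M_c)$, min–max
normalized to $[0,1]$ (an all-zero result stays all zero). Choices the
published Score-CAM formulation leaves open, and our defaults: zero-image
baseline for the score change; rectification before normalization (without
it, negative-weight channels invert the color semantics of the overlay);
`top_k = 64` channels ranked by spatial variance to bound the re-forward
count.

A heatmap is *concordant* with a lesion mask when its high-activation region
$A = \{\text{heatmap} \ge 0.5\}$ overlaps the mask by at least $\tau = 0.5$
of $|A|$ (both thresholds configurable and reported). The shuffled-mask
baseline — re-scoring the same heatmaps against randomly permuted masks —
gives the chance level of this statistic.

## Metrics

* Precision/recall/F1 are **support-weighted**, which makes weighted recall
  identically equal to accuracy. This convention is adopted because the
  study this package operationalizes reports recall exactly equal to
  accuracy while precision differs — the signature of support weighting
  (micro-averaging would force precision to equal accuracy as well; macro
  would generically break the recall identity).
* ROC AUC uses the midrank (trapezoidal) tie convention via the rank-sum
  identity; per-class AUCs are one-vs-rest, and the micro AUC pools all
  $4n$ (score, indicator) pairs into one binary problem. A class absent
  from the truth yields `NA` for its own AUC without blocking the micro AUC.
* `risk_monotonicity()` reports per-class mean risk scores and a strict
  monotonicity flag; `adjacency_confusion()` reports the fraction of errors
  between adjacent grades (the clinically benign error mode).

## Problem sizes and budgets

The test suite exercises two training scales, chosen so the full suite runs
in minutes on one CPU: a mechanism-recovery run (600 images split
400/100/100, tiny preset, ≤30 epochs — expected to reach ≥0.9 test accuracy
with strictly monotone risk means and above-chance Score-CAM concordance)
and an ablation run on the `"overlapping"` condition (360 images split
240/60/60, batch 16, 20 epochs, full vs. `no_progression` over 3 seeds,
sign check on High-Risk recall). Structural tests (gradient checks against
central finite
differences, the nested-loop attention oracle, exhaustive pair-counting AUC)
use micro configurations (width 12–16, 16-px images) where brute force is
exact and instant.

## Known limitations

* The base (224 px, width 768) configuration is fully functional but slow in
  R; no pretrained weights are bundled, and nothing in the package depends
  on them.
* The SFL encodes stage *identities*, not stage order (see above); ordinal
  structure enters through the loss targets.
* The ablation direction check is scale-sensitive. The contribution of the
  progression module was established at full scale (thousands of real
  images, a pretrained encoder); in the desk-scale harness, where tiny
  models train from scratch under short matched budgets, the extra depth of
  the SFL is an optimization cost as much as a representational benefit,
  and the sign check on High-Risk recall against `no_progression` can come
  out inverted even while the full model leads on overall accuracy and
  micro AUC. The harness reports the comparison as measured.
* The risk score is a relative severity index; no calibration layer is
  provided.
* The synthetic generator is a mechanism probe, not a clinical simulator;
  results on it do not transfer to endoscopic images.
* Single-threaded, dense linear algebra; no GPU, mixed precision, or
  learning-rate schedules (the protocol this package follows uses none).
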