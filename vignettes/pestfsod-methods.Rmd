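---
title: "Few-shot pest detection: model, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot pest detection: model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Agricultural pest monitoring needs detectors for many species, but most
species have only a handful of annotated images. Few-shot object detection
(FSOD) addresses this with a two-stage protocol: a detector is first trained
on *base* classes with plentiful annotations, then *fine-tuned* so that
*novel* classes — represented by only K annotated images each (here K = 3, 5
or 10) — become detectable while base-class accuracy is retained.
Performance is reported as mean average precision at IoU 0.5 over base
classes (bAP50), novel classes (nAP50) and all classes (mAP50).

`pestfsod` implements this pipeline end to end at desk scale, in pure R with
analytic gradients, together with a procedural scene generator that supplies
data with the statistical structure of small pest benchmarks: 20-odd
imbalanced classes, small and multi-scale targets, cluttered backgrounds.

# The method

Three components sit on top of a standard two-stage (proposal + RoI head)
detector.

## Cross-attention feature aggregation (FAM)

Query RoI features $F_q \in \mathbb{R}^{N_q \times D}$ are enriched with
support-set RoI features $F_s \in \mathbb{R}^{N_s \times D}$ through a
single-head scaled dot-product cross-attention:

$$Q = F_q W_Q,\quad K = F_s W_K,\quad V = F_s W_V,$$
$$A = \operatorname{softmax}\!\left(\frac{QK^\top}{\sqrt{d_k}}\right),\quad
F_{agg} = A V,\quad F_{enh} = F_q + \alpha\, F_{agg} W_O,$$

with bias-free projections, a learnable scalar $\alpha$ (initialized 0.5)
and an output map $W_O$ that restores the feature dimension when
$d_k \neq D$ ($W_O$ is identity-initialized when $d_k = D$). Support rows
are per-instance RoI features of the K-shot set, not class prototypes, so
attention can select individual exemplars. With $\alpha = 0$ the module is
an exact identity — the ablation arm used in testing.

## Class-weighted supervised contrastive loss (SCL)

Positive proposals are projected by a one-hidden-layer head to
$d_e$-dimensional embeddings and L2-normalized onto the unit sphere. With
$P(i)$ the same-label rows (excluding $i$) and $A(i)$ all other rows,

$$L_{SCL} = \sum_i \frac{w_{y_i}}{|P(i)|} \sum_{p \in P(i)}
  -\log \frac{\exp(z_i \cdot z_p/\tau)}{\sum_{a \in A(i)} \exp(z_i \cdot z_a/\tau)},
  \qquad w_y = 1/N_y,$$

where $N_y$ is the class count in the K-shot support set (counting in the
support set rather than the batch ties the imbalance correction to
dataset-level scarcity; at K-shot scale batch counts would be noise).
Anchors without positives are skipped, since their $1/|P(i)|$ normalizer is
undefined. The raw $1/N_y$ weights are used as written, with any overall
scale absorbed into $\lambda_2$. The temperature is $\tau = 0.2$ for every
shot. The head is used only during training.

## Multi-task objective

$$L_{total} = L_{cls} + L_{reg} + \lambda_1 L_{agg} + \lambda_2 L_{SCL}.$$

* $L_{cls}$ is focal loss,
  $-\frac1N\sum_i \alpha_{t,i}(1-p_{t,i})^\gamma \log p_{t,i}$, with
  $\gamma = 2$ and $\alpha_t$ the normalized inverse class frequency
  (background weight 1). With $\gamma = 0,\ \alpha_t = 1$ it reduces exactly
  to cross-entropy; both values are configurable because neither is pinned
  down by the protocol we follow.
* $L_{reg}$ is smooth-L1 on standard $(dx, dy, dw, dh)$ box-delta encodings
  with transition point $\beta = 1$, mean-reduced over boxes (mean rather
  than sum keeps the $\lambda$ balance independent of batch size).
* $L_{agg}$ regularizes the attention:
  $\frac{1}{N_q}\sum_{ij} a_{ij}\log a_{ij} + \frac{1}{N_q}\sum_{ij}|s_{ij}|$.
  Minimizing the first term *maximizes* attention entropy (weights spread
  over the support set) while the second shrinks raw scores. The two pull
  in opposite directions by design; we keep the printed 1:1 scaling. A
  documented sign ambiguity exists between the entropy-regularizer
  definition and the assembled loss in the source method: an
  entropy-*minimizing* reading would concentrate attention, contradicting
  its stated purpose, so the assembled form (negative entropy in the loss)
  is implemented, with `entropy_mode = "minimize"` exposing the other
  reading.
* Shot-dependent settings follow the published protocol: positive-IoU
  thresholds 0.6/0.7/0.8 and $\lambda_2$ = 0.2/0.5/0.5 for 3/5/10 shots.
  The protocol states one weight triple for two symbols; we read it as
  $\lambda_2$ and default $\lambda_1 = 0.5$ for all shots (configurable).

# Desk-scale detector

The contribution under test is the FAM/SCL/loss machinery, not a large
backbone, and no deep-learning runtime is assumed: everything is plain
matrix algebra with hand-derived gradients, each checked against finite
differences in the test suite.

* **Frozen random pyramid.** A 4-stage convolutional network
  (16/32/64/128 channels, seeded He-initialized random filters, ReLU,
  2×2 max-pooling) feeds an FPN-style top-down pathway projected to 12
  channels at strides 4/8/16. Random convolutional features preserve colour
  and local texture and are a standard frozen stand-in for a pretrained
  backbone at this scale; only detection-specific modules train.
* **RoI features.** RoI Align samples a 7×7 grid bilinearly; the flattened
  7·7·12 = 588-vector (unit L2 norm) is the RoI feature. Flattening, rather
  than spatial averaging, is deliberate: the regression head needs the
  spatial layout to recover box offsets, and averaged features would
  destroy it.
* **RPN-lite.** Dense anchors (3 scales at stride 4, 2 at stride 8, 1 at
  stride 16) are scored and regressed from 3×3-neighbourhood cell features,
  with separate weights per anchor type. Proposals keep both the
  delta-regressed box (deltas clamped to ±0.5) and the raw anchor:
  regression learned on base classes can mislocalize novel appearances,
  while the dense anchor alone often already clears IoU 0.5.
* **Appearance-invariant localization.** Both delta branches (RPN and RoI
  head) read per-channel spatially *standardized* features: each channel's
  per-RoI mean and scale are removed, leaving the spatial pattern. Box
  offsets do not depend on what colour an object is, and this is what lets
  localization trained on base classes transfer to novel classes.
  Consequently the regression branch reads pre-FAM features;
  classification and SCL read the FAM-enhanced features.
* **Fine-tuning extras.** New classifier columns are prototype-initialized
  (weight imprinting) from mean support features, rescaled to the mean norm
  of the trained base columns so novel logits start on the same confidence
  scale. The K-shot set doubles as (a) the FAM support bank, kept as the
  permanent support set at inference (the protocol does not specify
  test-time support handling), and (b) a source of cell-level class
  prototypes that emit additional *support-guided proposals* wherever a
  pyramid cell's neighbourhood feature matches a support prototype by
  cosine similarity — rescuing objects whose appearance the class-agnostic
  objectness never saw as a positive.
* **Inference.** Classifier confidence is tempered by RPN objectness
  (geometric mixing) to suppress confidently-classified clutter; the head
  is applied for 3 refinement rounds (re-pool, re-score, re-regress), and
  class-wise NMS at IoU 0.3 removes shifted duplicates (generated scenes
  cap same-class overlap well below this).
* **Optimization.** SGD with momentum 0.9, weight decay $10^{-4}$, global
  gradient-norm clipping at 5, step (×0.1 at ⅔ of iterations) or cosine
  schedules. Divergence (non-finite loss) stops training at the last good
  parameter state. The published GPU-scale schedule (lr 0.02, batch 4,
  18,000 iterations, evaluation every 3,000, fine-tuning lr 0.001) remains
  the documented default of `train_config()`; desk-scale runs use 600 base
  iterations at lr 0.1 and 300 fine-tuning iterations at lr 0.05 (cosine),
  sizes chosen so a full 10-seed protocol fits in minutes on one CPU core.
  Following the two-stage protocol's checkpoint rule, both stages evaluate
  mAP50 on a validation manifest at fixed intervals and keep the
  best-scoring checkpoint rather than the final iterate.
  Fine-tuning batches oversample images carrying novel-class instances
  (weight 2): the novel classifier columns start nearly fresh and need more
  gradient exposure than the already-trained base columns. Training
  proposals include interior part-crops of each object as explicit
  background negatives — on colour-homogeneous objects a sub-patch
  classifies like the whole object, and the classifier must learn that a
  partial box is not a detection.

# Synthetic scenes

`scene_spec()`/`generate_dataset()` emulate the structure of the 20-class
pest benchmark the method was designed for: configurable per-class image
counts (the packaged profile spans 92–400 training images per class, and
`scale_profile()` shrinks it while preserving the imbalance ratio),
small/multi-scale targets (default 16–40 px in 96×96 scenes), textured
backgrounds with unannotated clutter blobs, bounded same-class overlap, and
a `hard_background` camouflage knob blending objects toward the background
(off by default). Classes are procedural shapes (ellipse, rectangle,
triangle, diamond, blob) with saturated hues spread around the colour
wheel over a desaturated soil-coloured background, so classes are separable
in principle — a deliberate property: the sanity criterion "novel classes
are learnable from 10 shots" must be attainable when the method works.
Every object of an image belongs to the image's class (pest photos are
typically single-species), which makes per-class image counts equal the
requested profile exactly.

What the generator does **not** emulate: real insect appearance and pose,
intra-class stage variation (egg/larva/adult), inter-class visual
similarity gradients, lighting, occlusion beyond the overlap cap, or
label noise. Passing tests therefore demonstrate that the machinery —
episodes, attention, contrastive shaping, losses, evaluation — behaves
correctly and that the pipeline can learn novel classes from few shots on
separable data; they do not certify accuracy on real pest imagery.

# Evaluation

Greedy one-to-one matching per image and class (descending score, highest
unmatched IoU) at IoU > 0.5 — the positivity criterion is read strictly,
configurable to ≥ — feeds all-points interpolated AP (the area under the
monotone precision envelope, i.e. the continuous integral definition, not
11-point interpolation). bAP/nAP/mAP are unweighted means over base, novel
and all classes; classes with zero ground truths are excluded from means
with a warning, as their AP is undefined. Confusion matrices assign each
ground truth its best-IoU unmatched detection above threshold (any class),
with unmatched ground truths and detections booked against background; raw
counts are returned with an optional row-normalized view, since the
normalization convention in published figures is not stated.

# Numerical choices and degenerate inputs

* Softmax rows are computed max-shifted; $0\log 0 = 0$ in the entropy term.
* $p_t = 0$ in focal loss is clamped at $10^{-12}$ with a warning.
* Zero-norm contrastive embeddings raise an error naming the row.
* Empty support sets are an error in attention (undefined), and an
  all-singleton batch returns SCL 0 with a warning.
* Ties in target assignment go to the lower ground-truth index; object
  placement uses rejection sampling with 50 retries, then skips with a
  warning.
* Degenerate (zero-area) boxes have IoU 0 with a warning.

# Known limitations

* The frozen random backbone caps achievable accuracy; desk-scale AP
  numbers are internal sanity measures, not comparable to GPU-scale
  published accuracies on real data.
* When two novel classes share a shape and sit on adjacent hues, their
  mutual confusion is the binding constraint at 10 shots: novel AP50 for
  such pairs hovers around 0.5 rather than the 0.7–0.9 reached by
  visually distinct novel classes.
* Attention over the full support bank is quadratic in bank size; fine for
  K ≤ 10 and ≤ 20 classes.
* The support bank is the permanent inference-time support set; episodic
  test-time support sampling is not implemented.
* Single-head attention only, matching the method; multi-head is out of
  scope.
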