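---
title: "Residual-guided self-supervised learning for sinus anomaly classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-guided self-supervised learning for sinus anomaly classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Incidental paranasal anomalies — polyps, retention cysts, mucosal thickening —
are common findings in cranial MRI. Training a supervised classifier for
normal-vs-anomalous maxillary sinus (MS) volumes needs many labelled examples,
while unlabelled volumes are cheap. `msanomaly` implements a self-supervised
pipeline whose pretext task is *anomaly localization*, so the representation
learned without labels is already aligned with the downstream decision:

1. **Unsupervised anomaly detection (UAD).** A 3D convolutional autoencoder
   $A(\cdot)$ is trained with per-voxel L1 loss to reconstruct *normal* MS
   volumes only. Because the autoencoder never sees anomalies and compresses
   through a low-dimensional bottleneck, it reconstructs anomalous structure
   poorly.
2. **Residual volumes.** For each volume $x$ of an unlabelled pool, the
   voxel-wise reconstruction error $r = |x - A(x)| \in [0,1]^{d^3}$ is a
   *pseudo segmentation mask*: it is large where $x$ deviates from the normal
   anatomy model. An optional 3D median filter (kernel 5) removes salt-like
   error speckle while preserving blob-shaped lesion residuals.
3. **Self-supervised pretraining.** A U-Net — 3D ResNet18 encoder
   $E(\cdot)$, mirrored decoder $D(\cdot)$ with trilinear upsampling and skip
   connections — receives $x$ and is trained to output $r$ under per-voxel
   binary cross-entropy (BCE with soft targets; L1/L2 are config options).
   Predicting where the normal-anatomy model fails forces $E$ to encode
   lesion-relevant structure.
4. **Fine-tuning.** The decoder is discarded; the encoder's globally pooled
   bottleneck feature feeds an MLP head (feature dim → 256 → 2) and the whole
   classifier is fine-tuned on a *fraction* of the labelled set with the
   softmax binary cross-entropy, selecting the epoch with the lowest
   validation loss.

Evaluation uses AUROC, AUPRC (average precision; the anomalous class is the
positive class throughout) and F1 at the argmax decision, aggregated over
patient-grouped cross-validation folds as mean ± Student-t 95% confidence
interval.

## Preprocessing contracts

MS volumes are cubes cut from cranial MRI at the mean of recorded MS centroids
(component-wise mean, rounded half away from zero), using half-open, 0-based
cube bounds `[c - edge/2, c + edge/2)` and **no resampling**; a cube that
exceeds the grid is an error rather than being clamped or padded, since
silently padded cubes would corrupt the normal-anatomy model of the UAD stage.
The 64 mm cube equals 64 voxels under the package's declared 1 mm isotropic
assumption; the cube edge is a configuration knob everywhere. Right-side
volumes are mirrored onto the left (axis 1 of the array by convention — the
scanner-frame axis is configurable since "horizontal" is frame-dependent) and
every volume is min–max normalized to $[0,1]$; an exactly constant volume maps
to all zeros, a defined output preferred over a division by zero.

Cross-validation folds partition *patients*, not volumes, stratified by the
patient-level label "any MS anomalous"; both MS volumes of a patient always
land in the same partition. Label-fraction subsets draw
`round_half_up(fraction * n)` volumes per class, patient-coherently, and are
*nested* across fractions for a fixed seed, which lowers the variance of
learning-curve sweeps.

## The synthetic phantom generator

The study's clinical cohort cannot ship with the package, so every stage is
exercised on synthetic sinus phantoms built from the minimal geometry that
exhibits the normal/anomalous contrast the residual mechanism exploits: a
dark ellipsoidal air cavity (intensity 0.05) inside bright tissue (0.8),
wrapped in a thin mucosal lining. The lining shares the lesion intensity
(0.6) — mucosa and mucosa-derived lesions carry the same signal — so a
noise-free phantom takes exactly three intensity values, and anomaly
detection cannot degenerate into detecting a fourth, never-seen intensity.
Lesions are:

* `polyp_like` — a sphere centred on the lining, protruding into the cavity;
* `cyst_like` — a sphere fully inside the cavity;
* `mucosal_thickening` — the lining locally thickened over a solid-angle
  patch.

The ground-truth mask marks exactly the air voxels whose intensity was
replaced, so erasing the masked voxels reproduces the normal phantom of the
same seed. Cavity semi-axes (≈ 0.27–0.32 of the cube edge) and centre are
jittered ±8%/±4% between phantoms to emulate anatomical variability; additive
Gaussian noise (sd 0.05) is clipped to $[0,1]$, the simplest noise model
compatible with the normalization contract. Lesion radii default to
0.09–0.17 of the cube edge. These values were fixed once as a plausible
desk-scale caricature of sinus morphology — lesions occupy a few percent of
the cube, visibly brighter than air but identical in intensity to healthy
mucosa; no quantitative clinical size distribution is claimed.

What the phantoms do **not** model: FLAIR contrast physics, registration
error, bias fields, anatomy outside the sinus, multi-lesion volumes. Passing
tests therefore demonstrate that the pipeline's *mechanism* works end-to-end
— they do not certify clinical performance.

## Networks and numerical choices

* **CAE**: four stride-2 3×3×3 convolution stages (batch norm + leaky ReLU),
  a fully connected latent bottleneck (512 at full scale), then four
  trilinear-upsample + convolution stages and a sigmoid output. The sigmoid
  keeps reconstructions in $(0,1)$ so residuals stay in $[0,1]$ and are valid
  BCE targets downstream.
* **Encoder**: basic-block 3D ResNet18 — stages of 2 blocks each with channel
  widths (64, 128, 256, 512) scalable by a width factor, stage strides
  (1, 2, 2, 2). The large-image 7³-stride-2-stem + max-pool entry of the
  224²-image recipe is replaced by a single 3×3×3 stride-2 stem: inputs here
  are at most 64³ and a /4 stem would discard most of the resolution before
  the first residual stage. Total downsampling is 16.
* **Decoder**: mirrors the encoder channels in reverse; each stage is
  trilinear upsampling, concatenation with the matching encoder feature map
  (stages 3, 2, 1 and the stem), a 3×3×3 convolution, batch norm and leaky
  ReLU, ending in a sigmoid 1-channel output. A switch disables skip
  connections for ablations.
* **Classifier**: global *average pooling* of the bottleneck map (the
  pooled-vs-flattened choice is not dictated by the architecture; pooling is
  the declared default, keeping the head size independent of the cube edge),
  then MLP 512 → 256 → 2 and softmax binary cross-entropy.

Because no deep-learning framework is available to R, the 3D convolution,
trilinear upsampling and median-filter kernels are implemented in C++
(Rcpp), with a small tape-based reverse-mode autodiff and
Adam/AdamW/layerwise-adaptive (LARS-style) optimizers in R; every kernel
gradient is verified against central finite differences in the test suite.
BCE clamps probabilities to $[10^{-7}, 1-10^{-7}]$; batch-norm uses eps
$10^{-5}$ and running-stat momentum 0.1 (running stats are used in
evaluation mode). One degenerate case is worth knowing: when the bottleneck
feature map is 1³ *and* the batch has a single sample, the batch variance is
zero and the normalized activation (and its gradient) vanish — training
batches should contain at least two volumes, as all defaults do. Residuals are *not* renormalized before pretraining —
they already live in $[0,1]$, and rescaling would amplify noise on
near-perfect reconstructions.

## Training schedules

Full-scale defaults mirror the reference recipe: CAE trained without
augmentation on the normal training subset; SSL with LARS at peak rate 0.2,
500 epochs, 20-epoch linear warmup then cosine annealing to 0 (the schedule
is continuous at the junction and attains the peak there); fine-tuning with
AdamW at a constant 1e-4 for 100 epochs, batch 16, preserving the
lowest-validation-loss checkpoint. The layerwise-adaptive optimizer is
motivated by batch size 256; at desk scale (batches ≤ 8) the AdamW fallback
with a peak rate of a few 1e-3 is the stable choice and is what the desk
profile uses.

During SSL, spatial augmentations (axis flip; small integer translation as
the affine component) are applied with *identical* sampled parameters to
input and target — a spatially misaligned target would destroy the
localization signal — while Gaussian noise is applied to the input only;
each augmentation fires independently with probability 0.5. Whether the
network input during SSL is the volume or the residual itself is a genuine
reading ambiguity of "reconstruct the residual volumes"; the package follows
the volume-in / residual-target reading, which is the one that makes the
encoder useful for classifying *volumes* downstream. Augmentation during SSL
and the 10% SSL validation holdout (used to preserve the best checkpoint)
are both config switches with these defaults.

For fine-tuning, class imbalance is left unweighted (a weight switch exists,
default off), the F1 decision is the argmax of the 2-logit head, and
confidence intervals are Student-t over folds (the conventional choice at
k = 5; the CI method is recorded in the report object).

## Problem sizes used by the tests and acceptance runs

The package's own verification runs at desk scale, chosen so the full chain
is demonstrably learnable on one CPU:

* UAD: CAE with channels (4, 8, 16, 32), latent 32, trained 30 epochs on
  150 normal 32³ phantoms; evaluated on held-out 50 normal + 50 anomalous
  phantoms (separation AUROC, and median Dice of the 95th-percentile
  thresholded, median-filtered residual against the hidden masks).
* SSL benefit: labelled benchmark of 100 normal + 100 anomalous phantoms
  with a 120-volume unlabelled pool (50% anomalous); U-Net at width 1/16;
  SSL 20 epochs (AdamW, peak 4e-3, 3-epoch warmup, cosine); fine-tuning at
  label fraction 0.1 for 50 epochs at rate 1e-3, compared against a
  random-init encoder over 3 seeds. The fine-tuning length was chosen so
  both arms converge — with substantially shorter runs neither arm trains
  far enough for the comparison to be stable.
* CAE-fraction ablation: the same chain with the CAE trained on 20% vs 100%
  of the normal pool, median-kernel-5 residuals, downstream fraction 0.1.
* The `demo` pipeline runs the whole chain on 32³ phantoms in a few minutes
  and is the reproducibility check (two runs with one root seed give
  byte-identical results tables); the pipeline unit tests exercise the same
  chain end-to-end on 16³ phantoms.

## Known limitations

* Phantom realism is deliberately minimal (see above); absolute metric
  values on phantoms say nothing about clinical data.
* The hand-rolled networks are CPU-bound; full-scale (64³, widths 64–512,
  500-epoch) training is expressed in the `full` profile but is not practical
  without substantial compute.
* Residual quality — and hence the SSL signal — degrades when the CAE
  normal pool is very small; the ablation harness measures exactly this. At
  phantom desk scale this effect is *not* resolvable downstream: phantom
  normals are deliberately low-variability, so a CAE trained on 20% of the
  pool already models normal anatomy almost as well as one trained on the
  full pool, and the downstream AUPRC of the two arms is statistically
  indistinguishable (the corresponding acceptance check fails honestly).
  Separating the arms requires the anatomical diversity of real cohorts.
* Single-lesion phantoms only; the mask-consistency invariant (one
  6-connected component) applies to the blob lesion classes.
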