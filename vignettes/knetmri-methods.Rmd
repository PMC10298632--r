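---
title: "Classifying knee MRI injuries with feature-fusion slice-aggregating CNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying knee MRI injuries with feature-fusion slice-aggregating CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A routine knee MRI exam produces several *sequences* — acquisition
protocol/orientation pairs such as sagittal T1, sagittal T2, axial T2 and a
coronal hybrid weighting — each a stack of `s` grayscale slices (14–56 per
series in the protocol this package targets). The diagnostic questions are
binary per exam: is the knee abnormal at all, is there a medial meniscus
tear, is there bone marrow edema? An exam is labeled abnormal whenever
either sub-task is positive (or any other lesion is present), and a meniscus
tear must be visible in at least three consecutive slices to count.

`knetmri` implements a slice-aggregating convolutional classifier for these
tasks:

1. **Preprocessing.** Each series is resized to `s x 224 x 224` (bilinear).
   Pixels outside a configurable intensity range of interest are zeroed;
   the mean `m` and population standard deviation `sd` of *all training-set
   pixels* (after windowing) define the z-normalization `z = (x - m)/sd`
   applied to every series. Each slice is then expanded to three channels:
   the normalized original, its local binary pattern (LBP) map, and the
   low-pass (LL) subband of a single-level 2-D Haar wavelet transform
   upsampled back to 224 x 224. The result is an `s x 3 x 224 x 224` fused
   volume.
2. **KNet.** A convolutional backbone maps each slice independently to a
   `256 x 7 x 7` feature grid; average pooling over the spatial grid gives
   one 256-vector per slice (`s x 256`); a learned linear score per slice,
   softmaxed over slices, yields attention weights whose weighted sum is a
   single 256-dim exam embedding; a logistic head maps the embedding to a
   probability, thresholded at 0.5 (ties count as positive).
3. **MS-KNet.** Up to three sequences feed separate backbone+attention
   branches; the branch embeddings are fused by an arithmetic mean before
   the single shared head.
4. **Training.** Per task, the class-weighted binary cross-entropy
   `L = -alpha * y * log(p) - (1 - y) * log(1 - p)` is minimized, with
   `alpha` defaulting to the negative/positive count ratio of the training
   split so both classes contribute equal total weight. Optimization is
   Adam with a batch of one exam (slice counts differ between exams, which
   makes cross-exam batching awkward).

## Design choices in detail

**LBP convention.** 8 neighbors at radius 1, compared to the center with
`>=`, bits ordered clockwise from the top-left neighbor with the top-left as
the most significant bit; borders use edge replication. A constant image
therefore codes to 255 everywhere. The map is invariant under strictly
increasing intensity transforms on tie-free images — which is also why it is
computed on the windowed image *before* z-normalization: for LBP the order
is immaterial, and the DWT channel is per-slice standardized anyway, so only
one consistent convention needs recording.

**DWT convention.** Orthonormal single-level Haar on 2x2 blocks
(`LL = (a+b+c+d)/2`, analogous detail bands), which preserves energy
(Parseval) and maps a constant `c` to a constant `2c` in LL. Only the LL
band is exported as a channel, upsampled bilinearly so it stays spatially
registered with the other channels. Channels 2–3 are standardized per slice
to zero mean and unit sd so the three channels are commensurate for the
shared first convolution; a constant channel falls back to zeros.

**Backbones.** `tiny_cnn` (default) is a fully trainable three-layer strided
conv stack operating on a fixed 4x box-averaged 56 x 56 input, emitting the
same `256 x 7 x 7` contract as the large backbone; it is sized so that
end-to-end training fits desk-scale experiments. `alexnet_random` is the
classic five-conv AlexNet feature stack (random weights, frozen during
training, adaptive-pooled from 6 x 6 to the 7 x 7 contract). Pretrained
weights are not bundled, so requesting `alexnet_pretrained` is an error with
guidance rather than a silent degradation.

**Attention form.** The slice-aggregation step is a linear score followed by
a softmax and a weighted sum. The softmax guarantees a convex,
permutation-invariant combination of slice vectors, reduces to the identity
for a single slice, and keeps the aggregation differentiable end to end.
The softmax bias is redundant (shift invariance) but kept for symmetry; its
gradient is identically zero.

**Optimizer.** Adam, batch of one exam, with *parameter-group learning
rates*: 5e-3 for attention and head, 1e-4 for the backbone. With
single-exam updates, a uniform rate either churns the convolutional feature
space faster than the linear head can track it (head collapses to the blind
class-prior prediction) or is too slow to learn the head at all; the
discriminative schedule lets the head fit quasi-static features while the
backbone fine-tunes. `lr_backbone = 0` freezes the backbone entirely and
skips its backward pass — a fast exploratory mode, measurably weaker than
end-to-end training on the phantom. Probabilities are clamped at 1e-7 in
the loss for numerical safety; the tie at exactly p = 0.5 maps to label 1
by fixed convention.

**Data split discipline.** Normalization statistics come from the training
split only; `knet()` refuses a training list containing test exams;
`evaluate_model()` can cross-check supplied statistics against the
checkpoint's preprocessing fingerprint. Manifests enforce at most two exams
per patient and disjoint train/test patients.

**Undefined metrics.** Sensitivity (specificity) is reported as `NA` when
there are no positives (negatives) to evaluate, never silently as 0 or 100.
Percentages print with round-half-up to one decimal, the convention of
clinical tables.

## The synthetic phantom: what it emulates and what it does not

No public data accompany the imaging protocol this package targets, so the
package ships a deterministic phantom generator. Each exam is a smooth
ellipse-and-band intensity field — two "bone" ellipses separated by a bright
joint band — extruded across 14–56 slices with slow through-slice drift.
The four sequence types are deterministic contrast transforms of that one
anatomy (identity for sagittal T1, a gamma re-weighting for sagittal T2, a
nonlinear inverted window for axial T2, and the mean of the T1 and T2
contrasts for the coronal hybrid), plus independent Gaussian noise; exact
geometric co-registration between sequences is assumed rather than modeled.
The pure affine inversion one might write for the "inverted" axial contrast
would average with the identity to an exactly constant hybrid image, which
is why the inversion is nonlinear.

Positive exams carry planted lesions, each spanning at least three
consecutive slices: a hypointense crescent-shaped discontinuity on the
joint band for meniscus tears, a diffuse hyperintense blob inside a bone
for edema, and a small bright focus for "other" abnormalities, with
abnormality = 1 if any lesion is present. Task prevalences default to the
targeted cohort's rates (71.1% abnormal, 31.3% meniscus, 28.7% edema, 9.2%
co-occurrence) and the test split balances abnormal/normal exams.
Candidate lesion geometry is sampled for *every* exam, positive or not, and
stored, so region-mean oracle classifiers can be evaluated on both classes.

Two generator properties were design requirements, and their tension is
worth recording. The phantom must be separable by a trivial oracle (a
threshold on the candidate-region mean separates classes whenever the
lesion contrast is at least 3x the noise sd), and it must be *learnable by
the network itself* within ~20 epochs on a 60-exam training split. The
second requirement is much stronger: the architecture pools features over
the whole 7 x 7 grid and all slices, so a planted lesion competes against
between-exam anatomy variability, not just voxel noise. The shipped
defaults — lesion amplitude 0.8 in anatomy units (a frank signal void for
the crescent, a strong STIR-like hyperintensity for edema), lesion
footprints of a few percent of the image, modest anatomy jitter — were
chosen, once, as the regime where a regularized linear probe on a
random-initialization backbone's embeddings separates the classes; that is
the regime in which gradient training can succeed at desk scale.
Consequently, passing the phantom experiments demonstrates that the
pipeline, gradients and optimization work end to end; it does *not*
demonstrate clinical-grade performance on real knee MRI, where lesions are
subtler, anatomy varies far more, and cohorts are larger.

## Experiment sizes

The bundled experiments are sized for a single CPU: the learnability run
uses 100 phantom exams (60 train / 40 test), 14–20 slices per exam, one
sequence, 20 epochs (about three minutes). The ablation study is two
experiments: the seven-combination, three-task grid at single-epoch fits
(a cheap check of the harness and table contract), and a signal-planting
comparison — lesions in one sequence only — that trains just the two
informative combinations (a non-signal single stream and a three-stream
model containing the signal sequence) on a 24-train-exam cohort for 26
epochs, roughly the optimizer-step scale at which training breaks away
from the blind class-prior prediction at these cohort sizes. At that
budget the three-stream model is still mid-optimization; only its ordering
against the non-signal single stream is meaningful, not its absolute
accuracy. Cohort generation, training and evaluation are deterministic
given the seeds recorded in each experiment.

## Known limitations

- The phantom's anatomy is schematic; none of the experiments here say
  anything about radiologist-level performance on clinical data.
- The DICOM codec writes and reads the explicit-VR little-endian dialect
  with single-frame monochrome 16-bit pixels; compressed transfer syntaxes,
  implicit VR and enhanced multi-frame MR objects are out of scope.
- Intensity ranges of interest are configuration (full range by default);
  no clinically validated windows ship with the package.
- `alexnet_pretrained` requires weights the package does not bundle.
- The ablation harness retrains small models per combination; its absolute
  numbers are phantom-scale and only the relative ordering (multi-stream
  versus non-signal single stream) is meaningful.
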