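---
title: "Sparsified training for missing-sequence-robust tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsified training for missing-sequence-robust tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparseseg)
```

## The problem

Automatic tumor-core segmentation models for multi-sequence brain MRI
are usually trained on curated datasets in which every subject has all
four sequences: post-contrast T1-weighted (T1c), pre-contrast
T1-weighted (T1w), T2-weighted (T2w) and FLAIR.  Routine clinical data
are messier: in a typical surgical cohort roughly half of the patients
lack at least one of the three *secondary* sequences (T1w, T2w, FLAIR),
while T1c — the sequence on which the tumor is delineated — is always
present.  A network trained only on complete stacks degrades sharply
when a sequence it relied on is absent at inference.

`sparseseg` implements a training protocol that addresses this
directly: **sparsified training**.  Missing scans are represented as
zero-filled volumes on the common grid, and during training each
secondary channel of every sampled patch stack is independently
replaced by zeros with probability $p = 0.2$.  The normalization layers
are adjusted so that a zero-filled channel passes through *exactly*
unchanged; because available channels are whitened to zero mean and
unit variance over the brain support, an all-zero channel enters the
network at the mean intensity of available data, and a channel missing
in the original data is indistinguishable from one zeroed by the
augmentation.  The network therefore learns, within a single model, to
segment from any subset of inputs that contains T1c.

## The model

The segmentation network is a dual-pathway patch-based 3D CNN of the
DeepMedic family.  For an input window of $57^3$ voxels with a
downsample factor of 3:

* the *normal pathway* sees the central $25^3$ crop at full resolution;
* the *subsampled pathway* sees the whole window mean-pooled by 3
  (a $19^3$ input), giving it a threefold larger receptive field at a
  third of the resolution.

Each pathway stacks 8 valid $3^3$ convolutions (feature maps 30, 30,
40, 40, 40, 40, 50, 50) with leaky-ReLU activations; valid convolution
removes $8 \times 2 = 16$ voxels per axis, so the normal pathway emits
$9^3$ features and the subsampled pathway $3^3$, which are upsampled by
3 and concatenated.  Two 150-wide $1^3$ layers and a 2-class classifier
complete the 11 weighted layers.  The geometry is checked at
construction: per axis

$$\mathrm{output} = \left(\frac{\mathrm{input}}{ds} - 2L\right)\cdot ds,$$

with $L$ conv layers and factor $ds$; invalid combinations fail before
any training starts.  Training minimizes a soft Dice loss
$1 - (2\sum p y + \varepsilon)/(\sum p + \sum y + \varepsilon)$
(with $\varepsilon = 10^{-5}$) using Adam at an initial learning rate of
0.001, halved every 5000 iterations up to iteration 15 000 and every
1500 iterations thereafter, for 30 000 iterations; the last iteration
is the deliverable (validation data only monitor convergence — there is
no model selection).

The network, all layer gradients and the optimizer are implemented in
the package itself: batched 3D convolutions are lowered to an im2col
gather (C++) followed by one BLAS matrix product per layer, so training
and inference run on an ordinary CPU.  This also keeps every numeric
choice (initialization, activation slope, update rule) visible and
reproducible.  Batch normalization is deliberately absent: it would
re-introduce a dependence of a zero-filled channel's effective input on
the other channels, which the missing-aware normalization is designed
to avoid, and the CPU-scale networks train stably without it.

A `tiny` preset (3 conv layers of 8, 8, 16 maps per pathway, one
32-wide head layer, input $27^3$, same $9^3$ output; 500 iterations of
8 patches) scales the same topology down to a size for which the whole
experimental design runs on one CPU core in minutes.  Patch sampling
draws centers from the tumor core with probability 0.5 (a standard
choice under extreme class imbalance) and uniformly from the brain mask
otherwise; sparsification is applied per sampled patch stack — the
augmentation-layer reading — *after* normalization, with one draw
shared by the two pathway crops of a patch.

## Evaluation protocol

Segmentations are scored with Dice $2TP/(2TP+FP+FN)$, sensitivity
$TP/(TP+FN)$ and the undirected 95th-percentile Hausdorff distance
between the 6-connectivity boundaries, in mm under the anisotropic
voxel spacing.  We take the maximum of the two directed 95th
percentiles (linear interpolation between order statistics); a pooled
variant is available via `method = "pooled"`.  Conventions for
degenerate cases are explicit and flagged rather than silent:
Dice$(\emptyset,\emptyset) = 1$, sensitivity is undefined for an empty
manual mask, HD95 is undefined when either mask is empty.

Missing-sequence robustness is measured by *simulation*: on a test set
with complete imaging, all $2^3 = 8$ subsets of secondary channels are
zeroed in turn and every (subject, pattern) pair is scored.  Model
pairs are compared per pattern with two-sided Wilcoxon signed-rank
tests on subject-paired Dice scores (exact null distribution up to 25
non-zero differences without ties, normal approximation with continuity
and tie corrections otherwise; zero differences dropped, Pratt's method
behind a flag), followed by a *single* Bonferroni family over every
p-value computed in the run — the family size is reported in every
output table.  Models that differ only in sparsification share their
initialization and patch-sequence seeds, so each comparison isolates
the augmentation; the sparsification draws come from a separate seeded
stream, which also makes sparsified training with $p = 0$ bit-identical
to plain training.

## The phantom cohort

No clinical images ship with the package; a seeded generator produces
multi-channel phantoms that emulate the statistical structure the
method assumes:

* an ellipsoidal brain on a dark background (1 mm isotropic, $48^3$ by
  default);
* a tumor core — a randomly deformed blob (smooth radial perturbation
  of amplitude 0.25 around a 6–10 mm radius) fully inside the brain —
  decomposed into an enhancing rim (2 mm) and an enclosed necrotic
  core, with a 3 mm peritumoral halo;
* four channels rendering the same latent geometry with different
  contrasts: FLAIR bright over the whole core (0.92 vs 0.42 tissue)
  plus halo, T2w moderately bright core, T1w mildly dark core, and T1c
  with a subtle enhancing rim (0.56 vs 0.50 tissue) over a mildly dark
  core;
* a smooth multiplicative bias field (±20%, trilinear from a low-order
  control grid) and additive Gaussian noise (SD 0.08) per channel;
* per-subject missing patterns: with probability 0.5 a subject loses a
  non-empty subset of secondary channels, T2w-only being the most
  common pattern and T2w+FLAIR the next, as in routine surgical
  cohorts.

The *relative* contrast of the channels is the deliberate design
choice here.  The core is recoverable from T1c alone in principle, but
its per-voxel contrast is comparable to the noise, whereas FLAIR is
far above it — so a network trained greedily on complete stacks tends
to ride the FLAIR shortcut, which is exactly the failure mode
sparsified training exists to remove, and the redundancy needed to
compensate a missing FLAIR from the other channels is present by
construction.  Phantoms with an *equally* easy T1c make every model
trivially robust and can demonstrate nothing about the protocol.  The
generator is also deliberately simple in ways that matter for
interpreting results: tissue is homogeneous apart from bias and noise,
noise is Gaussian rather than Rician, there are no anatomical
structures, no scanner/site intensity shifts, and no registration
error.  Passing tests on these phantoms therefore demonstrate the
mechanics and the direction of the sparsified-training effect, not
clinical-grade accuracy.

Each subject's mask is the exact generating blob; a 2× oversampled
evaluation of the same implicit function provides an analytic core
volume against which the voxelized mask is validated.  All randomness
flows from one master seed through per-subject derived 31-bit seeds, so
cohorts reproduce file-by-file.

## Numerical choices and degenerate inputs

* Histogram landmarks at percentiles {1, 10, 20, …, 90, 99} of the
  pooled foreground intensities, mapped piecewise-linearly with linear
  extrapolation beyond the outer landmarks; fitting is done *before*
  any augmentation, on originally-available channels only.  Constant
  (degenerate) channels are rejected with an explicit error rather
  than silently producing non-monotone landmarks.
* Whitening statistics are computed over the brain mask only, so
  background air does not dominate the moments.
* Missing-channel detection uses the availability flag only, never an
  intensity heuristic — a legitimately dark channel is never dropped.
* Patch windows that extend beyond the volume are zero-padded; inference
  tiles the volume with stride equal to the output patch so every voxel
  is predicted exactly once, and tiles whose output window contains no
  brain voxels are left background (the core is inside the brain by
  construction).
* Grid consistency on input: shapes must match exactly, spacings to a
  relative tolerance of $10^{-4}$; volumes are used in the on-disk
  voxel lattice without reorientation (inputs are assumed co-registered
  and resampled upstream — registration, bias correction and skull
  stripping are out of scope).
* Manual masks must arrive binary; binarization of anti-aliased
  exports is the caller's responsibility.

## Problem sizes used by the test suite

The packaged experiments run at sizes chosen so the full suite
completes on one CPU core: the robustness experiment uses a fixed
48³ complete-imaging cohort of 40 training and 20 test phantoms, the
tiny preset, and three seed-matched model pairs (500 iterations, 8
patches per iteration); the determinism check of the experiment driver
uses a 32³ cohort with shorter training.  The direction of the
sparsified-training effect at this scale mirrors the full-scale
finding: without sparsification, zeroing the FLAIR analog at inference
can collapse the median test Dice, while the seed-matched sparsified
model retains most of its complete-input performance and complete-input
Dice changes by far less than the robustness gain.

## Known limitations

* The phantom cohort cannot stand in for clinical validation; absolute
  Dice values on phantoms are optimistic.
* The exact high-resolution crop size of the original full-scale
  implementation is not published; it is reconstructed here from the
  stated input size, downsample factor and output size, which the
  geometry rule satisfies uniquely.
* Whether the original augmentation sparsified per sampled patch or per
  loaded volume is not published; per-patch is the default reading and
  the draw is shared within a patch's pathway crops.
* Only the binary tumor core is segmented; multi-class subcompartments,
  CRF post-processing and ensembling are out of scope.
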