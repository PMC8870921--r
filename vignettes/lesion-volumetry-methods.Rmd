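---
title: "Methods: two-network lesion volumetry on T1/FLAIR MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-network lesion volumetry on T1/FLAIR MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multiple sclerosis produces focal demyelinating lesions in white matter that
appear hyperintense on FLAIR and hypointense on T1-weighted MRI. Total lesion
load, in cubic millimetres, is a standard quantitative marker of disease
burden. `lesionquant` computes it fully automatically from a co-acquired
T1-w/FLAIR pair with two convolutional networks used at two different
moments: the first extracts the brain from the T1-w image (skull-stripping),
the second segments lesions on the skull-stripped FLAIR. Lesion load is then
the count of segmented voxels times the voxel volume.

# Processing chain

Given a T1-w volume and a FLAIR volume of the same subject:

1. **Reslice** both to an isotropic 1 mm^3 grid with cubic (Catmull-Rom)
   interpolation. Extent is preserved to within one voxel per axis; masks
   always travel through nearest-neighbour resampling so they stay binary.
2. **Denoise** each axial slice with Perona-Malik anisotropic diffusion. The
   conductance decreases with gradient magnitude, so smoothing acts within
   tissue regions rather than across boundaries. The explicit scheme uses
   antisymmetric inter-pixel fluxes and replicated edges, so each slice's
   intensity sum is conserved to machine precision and constant slices are
   fixed points.
3. **Register** FLAIR to T1-w with a single in-plane rigid transform
   (translation + rotation about the slice centre), slices paired by index.
   The similarity is normalized mutual information, appropriate for the
   cross-modal T1/FLAIR pairing where corresponding tissues have unrelated
   intensities. Optimization is derivative-free Nelder-Mead over a
   multi-start grid at a 2x-downsampled, lightly blurred level, refined at
   full resolution with a simplex restart.
4. **Normalize**: per-slice z-score (each slice centred on its mean, scaled
   by its SD; constant background-only slices become zeros with a warning),
   resize in-plane to the network input shape, then min-max rescale the
   volume to [0, 1].
5. **Brain extraction**: the first U-Net produces a per-pixel brain
   membership on each T1-w slice; thresholding (default 0.5) gives the brain
   mask, which is transferred to FLAIR — the mask from T1-w strips both
   modalities.
6. **Bias correction**: a smooth multiplicative field is estimated inside
   the brain mask and divided out (below). The corrected, stripped FLAIR is
   then standardized against its normal-appearing tissue: the in-mask median
   maps to 0.5 and values clamp to [0, 1]. A min-max rescale here would
   anchor the scale on the brightest remaining structure — the lesions
   themselves, or, in a lesion-free subject, normal brain — making the
   lesion network's input scale depend on the very quantity being measured;
   the median anchor is load-invariant and handles lesion-free subjects.
7. **Lesion segmentation**: the second U-Net produces lesion memberships on
   the standardized stripped FLAIR; thresholding and intersection with
   the brain mask give the lesion mask (no lesion voxel can fall outside the
   brain).
8. **Quantification**: the lesion mask is resampled back to the 1 mm^3
   working grid with nearest-neighbour interpolation and the voxels are
   counted, so the reported number is mm^3 of physical space regardless of
   the processing resolution.

Every stage appends its parameters to a provenance record in the result, so
a run can be replayed from its output alone.

# The network

One configurable 2D U-Net serves both tasks. Encoder blocks apply two 3x3
same-padded convolutions, each followed by batch normalization (on by
default, switchable) and ReLU, then a 2x2 stride-2 max-pool; the number of
feature maps starts at `base_channels` and doubles at each of `depth`
pooling levels. Decoder blocks mirror this with non-learned 2x
nearest-neighbour up-sampling followed by a 3x3 convolution, concatenation
with the matching encoder feature map, and two further convolutions. A 1x1
convolution with a sigmoid produces the membership map. Same-padding keeps
every feature map at the input resolution, so skip concatenation needs no
cropping and the output shape always equals the input shape.

The implementation is self-contained: activations are stored as
`(rows x cols x batch) x channels` matrices, convolutions and their adjoints
are direct C++ kernels (with runtime-dispatched AVX2/FMA variants), and the
backward pass is exact — the test suite checks analytic gradients against
central differences at every layer type.

Training follows a fixed protocol for both networks: binary cross-entropy,
Adam with learning rate 0.001, batch size 32, up to 60 epochs, no
augmentation, no early stopping, no learning-rate schedule. Metrics logged
per epoch (loss, Dice, accuracy, precision, sensitivity, specificity on the
training and validation sets) are computed by the same metrics module used
for final evaluation, with predictions binarized at 0.5. Cross-validation
uses repeated seeded random 80:20 splits at the *subject* level (never the
slice level, which would leak neighbouring slices of one subject across the
split).

One numerical choice matters for rare-class convergence: a freshly built
network starts with a zero head bias, i.e. a prior membership of 0.5
everywhere, and with lesions occupying under 1% of voxels plain BCE spends
many epochs just driving the background down. `train_model` therefore
initializes the head bias to the empirical foreground log-odds of the
training targets before the first step. This changes no optimum — only the
starting point — and cuts the background-suppression plateau to nothing.

# Bias-field model

The scanner's B1 inhomogeneity is modelled as a smooth multiplicative field.
The estimator fits a low-order 3D polynomial (default order 3) to the log
intensities inside the brain mask, exponentiates the fitted surface, and
normalizes it to mean 1 over the mask; the correction divides the image by
the field. The fit is made robust by a trimmed refit: after the initial
least-squares pass, voxels whose residuals exceed 2.5 robust SDs (MAD) are
excluded and the surface is refitted, twice. Without this, focal
hyperintense structure — exactly the lesions the pipeline is trying to
measure — locally inflates the field and is dimmed by the division; with
high lesion load the dimming is large enough to cost 20-30% of measured
volume downstream. The trimmed fit anchors the surface to the smooth tissue
background instead. An N4-style B-spline fit could be slotted behind the
same contract (smooth, strictly positive, mean 1 over the mask); the
polynomial surface is self-contained and recovers the slowly varying fields
the generator injects at r > 0.99.

# The phantom generator

All training and testing runs on synthetic head phantoms with exact ground
truth. A phantom is an ellipsoidal brain (default semi-axes 25 x 21 x 8.5 mm)
inside a 2 mm skull-like shell on a 64 x 64 x 20 grid at 1 mm^3, with 1-3
spherical lesions of radius 3.5-6 mm placed fully inside the brain. The two
channels encode the modality contrast logic: on T1-w the shell is bright
(0.95), brain mid-grey (0.65), lesions hypointense (0.45); on FLAIR the
background and shell are suppressed (0.05 / 0.25), brain mid-grey (0.45),
lesions hyperintense (0.85). Corruption: a multiplicative bias field
(in-plane ramp 0.8-1.2 by default, random higher-order terms available), an
in-plane rigid misalignment of the FLAIR channel (up to 5 mm / 0.1 rad), and
additive Gaussian noise (SD 0.02). Ground-truth masks stay clean and
aligned to the T1-w grid; the true lesion volume is the exact voxel count of
the truth mask, and the sphere centres and radii are exported so tests can
re-derive it by independent enumeration.

Everything is deterministic given the seed; a cohort derives one seed per
case.

What the phantom deliberately does not emulate: MR sequence physics, partial
volume (tissue intensities are piecewise constant before corruption), Rician
noise, anatomical shape variability, confluent or periventricular lesion
geometry, and CSF. Passing tests on phantoms therefore demonstrate that the
chain is implemented correctly and can be learned end-to-end — not that the
shipped configuration reaches clinical-grade accuracy on real MRI, which
requires training on real annotated data at 256 x 256 resolution.

# Problem sizes used by tests and the acceptance script

Networks at phantom scale are depth 3 with 4 base channels (8 for the
overfit check), inputs 64 x 64. The learning checks train on a 10-case
cohort with two 80:20 repeats (brain: 30 epochs; lesion: 15 — the lesion
net, helped by the log-odds head initialization, converges faster than the
brain net, whose Dice target is stricter); the end-to-end check trains on 16
cases (brain 15, lesion 40 epochs) and evaluates on 10 held-out phantoms.
These sizes are the package's chosen desk-scale study conditions; the
protocol ceiling of 60 epochs is exercised by the overfit check. On real
256 x 256 data one would use the full-size defaults (`unet_config()`:
depth 5, 16 base channels, 60 epochs) and expect hours, not minutes, of
training per model.

# Conventions and degenerate inputs

* Metrics with empty denominators (e.g. Dice of two empty masks) return 1
  flagged with a `degenerate` attribute: a lesion-free subject predicted
  lesion-free is agreement, and flagging keeps convention distinguishable
  from measurement.
* Constant slices z-score to zeros with a warning; constant volumes min-max
  to zeros with a warning. Neither aborts a pipeline run.
* Masks pass through every resampling step with nearest-neighbour
  interpolation and are re-validated as binary.
* Membership thresholds are fixed at 0.5 by default and exposed everywhere;
  mask size is non-increasing in the threshold.
* Bland-Altman agreement reports bias, 1.96 SD limits of agreement and the
  squared Pearson correlation (the conventional R^2 of an agreement scatter),
  with differences oriented automatic minus manual.

# Open design points, resolved

* **One transform per volume, not per slice.** Slices are acquired as a
  stack and paired by index across modalities; a single in-plane transform
  matches that geometry and is far better conditioned than 20 independent
  3-parameter fits on single slices.
* **Cross-validation as repeated random subsampling.** "80:20, repeated"
  is implemented as independent seeded draws rather than a rotation of
  fixed folds; with repeats much smaller than the number of possible splits
  the two designs estimate the same quantity.
* **Volume counted on the working grid.** The lesion mask is brought back
  to the 1 mm^3 grid before counting, so voxel count equals mm^3 and the
  in-plane processing shape (256 x 256 in the full-size configuration,
  64 x 64 at phantom scale) does not change the reporting unit.
* **Batch normalization in both networks**, switchable per config; only the
  brain net strictly requires it in the original two-figure presentation,
  and it measurably speeds phantom-scale convergence for both.

# Known limitations

* Slice-wise per-slice z-scoring couples normalized lesion contrast to the
  slice's lesion area. At 64 x 64 phantom scale, where a lesion can occupy
  several percent of a slice, this was the main generalization burden on
  the lesion net; the median-anchored tissue standardization removes the
  volume-level part of the coupling, and at clinical 256 x 256 resolution
  the residual per-slice effect is an order of magnitude smaller.
* The registration model is rigid and in-plane only; through-plane motion
  and deformable anatomy are out of scope.
* The bias model is a global polynomial; fields with sharp local structure
  would need the N4-style adapter.
* Volumes are reported without connected-component analysis or per-lesion
  counts; the quantity of interest is total load.
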