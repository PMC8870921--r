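# lesionquant

Automatic quantification of white-matter lesion load on brain MRI of
multiple sclerosis patients, from a co-acquired T1-weighted/FLAIR pair, using
two convolutional networks at two different moments: a 2D U-Net that
extracts the brain on T1-w slices (skull-stripping), and a second U-Net that
segments lesions on the skull-stripped FLAIR. Lesion load is reported the
way radiology reports it: the count of segmented voxels on a 1 mm³ grid,
i.e. mm³.

The full chain is implemented and testable end to end:

* **Preprocessing** — isotropic reslicing (cubic interpolation), slice-wise
  Perona–Malik anisotropic diffusion, in-plane rigid registration of FLAIR
  to T1-w by normalized mutual information, per-slice z-score
  normalization, in-plane resize, min–max rescaling to [0, 1], and robust
  polynomial bias-field estimation/correction.
* **Networks** — one configurable U-Net encoder–decoder (3×3 same-padded
  convolutions, batch normalization, ReLU, 2×2 max-pooling, 2× up-sampling
  with skip concatenation, sigmoid head) serving both tasks. Forward and
  backward passes are authored in the package with direct C++ convolution
  kernels; training is binary cross-entropy with Adam (lr 0.001, batch 32,
  up to 60 epochs) and repeated subject-level 80:20 cross-validation.
* **Quantification and agreement** — confusion-based Dice, accuracy,
  precision, sensitivity, specificity; voxel-count volumetry; Bland–Altman
  bias, limits of agreement and R² between automatic and reference volumes.
* **Phantoms** — a synthetic head generator (ellipsoidal brain, skull-like
  shell, FLAIR-hyperintense/T1-hypointense spherical lesions, noise, bias
  field, known FLAIR misalignment) with exact ground truth, so every stage
  is trainable and testable without any external data.

In the standard notation: with voxel-wise counts TP/FP/FN/TN,
`Dice = 2TP / (2TP + FP + FN)`, and lesion load `V = |{v : M(v) = 1}| ·
s_x s_y s_z` for the thresholded membership mask `M` (threshold 0.5).
Bland–Altman agreement is `bias = mean(V_auto − V_ref)` with limits
`bias ± 1.96 · SD`.

## Worked example

```r
library(lesionquant)

# one synthetic subject with known ground truth
case <- make_phantom(phantom_spec(seed = 7))
case$true_lesion_volume_mm3
#> [1] 699
case$injected_transform
#> <rigid2d tx=4.561 mm, ty=-4.573 mm, theta=-0.031234 rad>

# recover the injected FLAIR misalignment (cross-modal NMI registration)
reg <- register_rigid_inplane(case$flair, case$t1)
reg$transform
#> <rigid2d tx=-4.593 mm, ty=4.446 mm, theta=0.024415 rad>
rigid_inverse(case$injected_transform)   # what perfect recovery would be
#> <rigid2d tx=-4.702 mm, ty=4.428 mm, theta=0.031234 rad>

# quantify the ground-truth mask and score a perturbed copy of it
lesion_volume(case$lesion_truth)
#> [1] 699
noisy <- case$lesion_truth
noisy$data[which(noisy$data == 1)[1:40]] <- 0   # delete 40 lesion voxels
seg_metrics(noisy, case$lesion_truth)
#>        dice    accuracy   precision sensitivity specificity
#>   0.9705449   0.9995117   1.0000000   0.9427754   1.0000000
```

The recovered transform matches the inverse of the injected one to about
0.1 mm in translation; the deleted 40 of 699 lesion voxels show up exactly
as sensitivity 659/699 = 0.943 with precision 1.

Training and the full pipeline follow the same pattern
(`prepare_training_data()` → `build_unet()` → `train_model()` /
`crossval()` → `run_pipeline()`); at phantom scale a model trains in
minutes on one CPU. A command-line wrapper with `make-phantoms`,
`preprocess`, `train-brain`, `train-lesion`, `segment`, `evaluate` and
`agreement` subcommands is installed at
`system.file("cli", "lesionquant.R", package = "lesionquant")`.

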