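#' Pipeline configuration
#'
#' Parameters of the end-to-end two-network chain: working resolution,
#' denoising, registration, model input shape, bias-field order, and the
#' membership threshold applied to both networks' outputs.
#'
#' @param target_spacing Working voxel spacing in mm (default 1 mm^3).
#' @param diffusion A [diffusion_config()]; the default (`kappa = 0.1`) suits
#'   intensities on a roughly `[0, 1]` scale.
#' @param model_shape In-plane shape `(rows, cols)` expected by the networks
#'   (default `c(256, 256)`).
#' @param threshold Membership threshold in `(0, 1)` for binarizing both
#'   networks' probability maps (default 0.5).
#' @param bias_order Polynomial order of the bias-field estimate (default 3).
#' @param registration_max_iter Optimizer iteration cap per resolution level.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target_spacing = c(1, 1, 1),
                            diffusion = diffusion_config(iterations = 5,
                                                         kappa = 0.1),
                            model_shape = c(256, 256),
                            threshold = 0.5,
                            bias_order = 3,
                            registration_max_iter = 300) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  structure(list(target_spacing = as.numeric(target_spacing),
                 diffusion = diffusion,
                 model_shape = as.integer(model_shape),
                 threshold = threshold,
                 bias_order = as.integer(bias_order),
                 registration_max_iter = as.integer(registration_max_iter)),
            class = "pipeline_config")
}

same_spacing <- function(a, b) isTRUE(all.equal(as.numeric(a), as.numeric(b)))

# Standardize a skull-stripped volume against its normal-appearing tissue:
# the in-mask median maps to 0.5, values clamp to [0,1]. Unlike a min-max
# rescale this does not anchor on the brightest structure, so the lesion
# network sees the same brain/lesion scale whether a subject has a heavy
# load or none at all.
scale_to_tissue <- function(v, mask) {
  med <- stats::median(v$data[mask$data == 1])
  if (!is.finite(med) || med <= 0)
    return(suppressWarnings(minmax_rescale(v)))
  volume(pmin(pmax(v$data / med * 0.5, 0), 1) * mask$data, v$spacing)
}

# shared image chain: reslice -> diffuse -> (z-score -> resize -> min-max)
normalize_for_model <- function(v, cfg) {
  v <- zscore_normalize(v)
  if (!identical(dim(v$data)[1:2], cfg$model_shape))
    v <- resize_inplane(v, cfg$model_shape, "spline")
  minmax_rescale(v)
}

#' Threshold a membership map into a binary mask
#'
#' Runs the network slice-wise over the volume and binarizes the membership
#' at `threshold` (voxels with membership `>= threshold` become 1).
#'
#' @param m A `unet_model`.
#' @param v A preprocessed `volume` whose in-plane shape matches the model.
#' @param threshold Membership threshold in `(0, 1)`.
#' @return List with `membership` (a probability-map `volume`) and `mask`
#'   (a binary `volume`).
#' @export
predict_mask <- function(m, v, threshold = 0.5) {
  stopifnot_volume(v)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  prob <- eval_in_chunks(m, v$data)
  membership <- as_probability_map(volume(prob, v$spacing))
  mask <- as_binary_mask(volume(array(as.numeric(prob >= threshold), dim(prob)),
                                v$spacing))
  list(membership = membership, mask = mask)
}

#' Run the full two-network segmentation pipeline
#'
#' Executes the complete chain on a co-acquired T1-w/FLAIR pair: reslice both
#' volumes to the working resolution, denoise by anisotropic diffusion,
#' rigidly register FLAIR to T1-w in plane, z-score normalize / resize /
#' min-max rescale, predict the brain mask on T1-w, transfer it to FLAIR
#' (skull-stripping), estimate and divide out the bias field inside the
#' brain, predict lesion membership on the stripped FLAIR, threshold, and
#' constrain lesions to the brain. The lesion mask is resampled back to the
#' working (1 mm^3) grid before voxels are counted, so the reported volume is
#' in mm^3 of physical space.
#'
#' @param t1,flair `volume`s of the same subject.
#' @param brain_model,lesion_model Trained `unet_model`s.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `brain_mask`, `lesion_mask` (binary
#'   volumes on the working grid), `lesion_membership` (probability map on
#'   the model grid), `lesion_volume_mm3`, `registration` (the fitted
#'   [rigid2d()]), and `provenance` (ordered list of applied steps with
#'   parameters).
#' @export
run_pipeline <- function(t1, flair, brain_model, lesion_model,
                         config = pipeline_config()) {
  stopifnot_volume(t1, "t1"); stopifnot_volume(flair, "flair")
  cfg <- config
  prov <- list()
  note <- function(step, ...) prov[[length(prov) + 1L]] <<- c(list(step = step), list(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. reslice to working resolution
  stage("reslice", {
    if (!same_spacing(t1$spacing, cfg$target_spacing))
      t1 <- reslice_isotropic(t1, cfg$target_spacing)
    if (!same_spacing(flair$spacing, cfg$target_spacing))
      flair <- reslice_isotropic(flair, cfg$target_spacing)
  })
  note("reslice", target_spacing = cfg$target_spacing)
  ref_dim <- dim(t1$data)

  # 2. anisotropic diffusion
  stage("diffuse", {
    t1 <- anisotropic_diffuse(t1, cfg$diffusion)
    flair <- anisotropic_diffuse(flair, cfg$diffusion)
  })
  note("diffuse", iterations = cfg$diffusion$iterations,
       kappa = cfg$diffusion$kappa, dt = cfg$diffusion$dt,
       conductance = cfg$diffusion$conductance)

  # 3. rigid in-plane registration of FLAIR to T1-w
  reg <- stage("register",
               register_rigid_inplane(flair, t1,
                                      max_iter = cfg$registration_max_iter))
  flair <- reg$aligned
  note("register", tx = reg$transform$tx, ty = reg$transform$ty,
       theta = reg$transform$theta, nmi = reg$nmi)

  # 4. normalize + resize to the model grid
  t1m <- stage("normalize", normalize_for_model(t1, cfg))
  flairm <- stage("normalize", normalize_for_model(flair, cfg))
  note("normalize", model_shape = cfg$model_shape)

  # 5. brain extraction on T1-w, mask transferred to FLAIR
  bp <- stage("brain_mask", predict_mask(brain_model, t1m, cfg$threshold))
  note("brain_mask", threshold = cfg$threshold)
  t1s <- stage("skull_strip", apply_mask(t1m, bp$mask))
  flairs <- stage("skull_strip", apply_mask(flairm, bp$mask))
  note("skull_strip")

  # 6. bias-field correction inside the brain
  if (sum(bp$mask$data) > 0) {
    field <- stage("bias_correct",
                   estimate_bias_field(flairs, bp$mask, cfg$bias_order))
    flairs <- stage("bias_correct", correct_bias(flairs, field))
    flairs <- scale_to_tissue(flairs, bp$mask)
    note("bias_correct", order = cfg$bias_order)
  } else {
    note("bias_correct", skipped = "empty brain mask")
  }

  # 7. lesion membership on stripped FLAIR; lesions constrained to the brain
  lp <- stage("lesion_mask", predict_mask(lesion_model, flairs, cfg$threshold))
  lesion_model_grid <- as_binary_mask(volume(lp$mask$data * bp$mask$data,
                                             lp$mask$spacing))
  note("lesion_mask", threshold = cfg$threshold)

  # 8. back to the working grid, then voxel-count volumetry
  to_ref <- function(mask) {
    if (!identical(dim(mask$data)[1:2], ref_dim[1:2]))
      mask <- resize_inplane(mask, ref_dim[1:2], "nearest")
    as_binary_mask(volume(mask$data, cfg$target_spacing))
  }
  brain_ref <- stage("resample_back", to_ref(bp$mask))
  lesion_ref <- stage("resample_back", to_ref(lesion_model_grid))
  vol <- lesion_volume(lesion_ref)
  note("quantify", lesion_volume_mm3 = vol)

  structure(list(brain_mask = brain_ref,
                 lesion_mask = lesion_ref,
                 lesion_membership = lp$membership,
                 lesion_volume_mm3 = vol,
                 registration = reg$transform,
                 provenance = prov),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: lesion volume %.1f mm^3, brain %d voxels, %d steps>\n",
              x$lesion_volume_mm3, sum(x$brain_mask$data), length(x$provenance)))
  invisible(x)
}

#' Build network-ready training data from phantom cases
#'
#' Applies the same image chain the pipeline uses at inference time, paired
#' with the phantoms' exact ground truth. For the brain task the input is the
#' preprocessed T1-w and the target the true brain mask; for the lesion task
#' the input is the skull-stripped (by the true brain mask), bias-corrected
#' FLAIR and the target the true lesion mask. FLAIR is aligned with the known
#' injected transform, mirroring training corpora that ship already
#' co-registered.
#'
#' @param cases List of `phantom_case` objects from [make_dataset()].
#' @param target `"brain"` or `"lesion"`.
#' @param cfg A [pipeline_config()]; set `model_shape` to the phantom's
#'   in-plane shape to train at native resolution.
#' @return List of subjects, each `list(x = slices, y = masks)`, suitable for
#'   [train_model()] / [crossval()].
#' @export
prepare_training_data <- function(cases, target = c("brain", "lesion"),
                                  cfg = pipeline_config(model_shape = c(64, 64))) {
  target <- match.arg(target)
  lapply(cases, function(cs) {
    if (target == "brain") {
      v <- cs$t1
      if (!same_spacing(v$spacing, cfg$target_spacing))
        v <- reslice_isotropic(v, cfg$target_spacing)
      v <- anisotropic_diffuse(v, cfg$diffusion)
      v <- suppressWarnings(normalize_for_model(v, cfg))
      y <- cs$brain_truth
    } else {
      v <- apply_transform(cs$flair, rigid_inverse(cs$injected_transform),
                           "spline")
      if (!same_spacing(v$spacing, cfg$target_spacing))
        v <- reslice_isotropic(v, cfg$target_spacing)
      v <- anisotropic_diffuse(v, cfg$diffusion)
      v <- suppressWarnings(normalize_for_model(v, cfg))
      brain <- cs$brain_truth
      if (!identical(dim(brain$data)[1:2], cfg$model_shape))
        brain <- as_binary_mask(resize_inplane(brain, cfg$model_shape, "nearest"))
      v <- apply_mask(v, brain)
      field <- estimate_bias_field(v, brain, cfg$bias_order)
      v <- correct_bias(v, field)
      v <- scale_to_tissue(v, brain)
      y <- cs$lesion_truth
    }
    if (!identical(dim(y$data)[1:2], cfg$model_shape))
      y <- as_binary_mask(resize_inplane(y, cfg$model_shape, "nearest"))
    list(x = v$data, y = y$data)
  })
}
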