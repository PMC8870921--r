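#' Synthetic head-phantom specification
#'
#' Defines the geometry, contrasts and corruptions of a synthetic T1-w/FLAIR
#' head phantom with exact ground truth: an ellipsoidal brain inside a bright
#' skull-like shell, spherical white-matter lesions that are hyperintense on
#' FLAIR and hypointense on T1-w, additive Gaussian noise, a smooth
#' multiplicative bias field, and a known in-plane rigid misalignment of the
#' FLAIR channel relative to T1-w.
#'
#' Defaults describe a compact 64 x 64 x 20 head at 1 mm^3 - large enough for
#' every pipeline stage (shell, tissue, lesion contrast, bias, misalignment)
#' to be present and analytically checkable, small enough to train on a
#' single CPU.
#'
#' @param dim Grid shape `(rows, cols, slices)`.
#' @param spacing Voxel spacing in mm.
#' @param brain_semiaxes Ellipsoid semi-axes of the brain in mm.
#' @param skull_thickness Shell thickness in mm outside the brain surface.
#' @param lesion_count_range Inclusive integer range of lesion count.
#' @param lesion_radius_range Lesion sphere radius range in mm.
#' @param t1_intensity,flair_intensity Named vectors with `background`,
#'   `brain`, `lesion`, `skull` tissue intensities. The defaults encode the
#'   modality contrast logic: lesions darker than brain on T1-w, brighter
#'   than brain on FLAIR (whose background/CSF signal is suppressed).
#' @param noise_sigma SD of additive Gaussian noise.
#' @param bias_amplitude Peak relative deviation of the multiplicative bias
#'   field from 1 (0.2 gives a field spanning about 0.8-1.2).
#' @param bias_order Polynomial order of the injected field; order 1 is a
#'   deterministic in-plane ramp, higher orders add seeded random terms.
#' @param misalign_max_shift Maximum absolute in-plane translation (mm) of
#'   the injected FLAIR misalignment.
#' @param misalign_max_theta Maximum absolute in-plane rotation (rad).
#' @param seed Integer seed; a fixed seed yields a bit-identical phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(64, 64, 20),
                         spacing = c(1, 1, 1),
                         brain_semiaxes = c(25, 21, 8.5),
                         skull_thickness = 2,
                         lesion_count_range = c(1, 3),
                         lesion_radius_range = c(3.5, 6),
                         t1_intensity = c(background = 0.05, brain = 0.65,
                                          lesion = 0.45, skull = 0.95),
                         flair_intensity = c(background = 0.05, brain = 0.45,
                                             lesion = 0.85, skull = 0.25),
                         noise_sigma = 0.02,
                         bias_amplitude = 0.2,
                         bias_order = 1,
                         misalign_max_shift = 5,
                         misalign_max_theta = 0.1,
                         seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 8), all(spacing > 0),
            all(brain_semiaxes > 0), skull_thickness >= 0,
            lesion_count_range[1] >= 0,
            diff(lesion_count_range) >= 0,
            lesion_radius_range[1] > 0,
            noise_sigma >= 0, bias_amplitude >= 0, bias_order >= 1,
            misalign_max_shift >= 0, misalign_max_theta >= 0)
  spec <- as.list(environment())
  spec$dim <- as.integer(dim)
  spec$seed <- as.integer(seed)
  structure(spec, class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# physical voxel-centre coordinate arrays (mm), one array per axis
coord_arrays <- function(dim, spacing) {
  ax <- function(k) (seq_len(dim[k]) - 0.5) * spacing[k]
  list(x = array(rep(ax(1), times = dim[2] * dim[3]), dim),
       y = array(rep(rep(ax(2), each = dim[1]), times = dim[3]), dim),
       z = array(rep(ax(3), each = dim[1] * dim[2]), dim))
}

ellipsoid_field <- function(co, center, semiaxes) {
  ((co$x - center[1]) / semiaxes[1])^2 +
  ((co$y - center[2]) / semiaxes[2])^2 +
  ((co$z - center[3]) / semiaxes[3])^2
}

injected_bias_field <- function(spec, co, center) {
  # normalized coordinates in [-1, 1] over the grid extent
  ext <- spec$dim * spec$spacing
  xn <- 2 * co$x / ext[1] - 1
  yn <- 2 * co$y / ext[2] - 1
  zn <- 2 * co$z / ext[3] - 1
  f <- 1 + spec$bias_amplitude * xn   # deterministic in-plane ramp
  if (spec$bias_order >= 2) {
    monos <- list(yn, zn, xn * yn, xn^2, yn^2, xn * zn, yn * zn, zn^2)
    coef <- stats::runif(length(monos), -1, 1) * spec$bias_amplitude / 2
    for (i in seq_along(monos)) f <- f + coef[i] * monos[[i]]
  }
  pmax(f, 0.05)
}

#' Generate one phantom case
#'
#' Deterministic for a fixed `spec$seed`. The T1-w channel is kept on the
#' reference grid; the FLAIR channel is corrupted by a seeded in-plane rigid
#' misalignment before noise is added. Ground-truth brain and lesion masks
#' stay clean and aligned to the T1-w grid, and the true lesion volume is the
#' exact voxel count of the lesion mask times the voxel volume.
#'
#' @param spec A [phantom_spec()].
#' @param max_retries Placement retries per lesion before giving up.
#' @return A `phantom_case` list: `t1`, `flair` (corrupted volumes),
#'   `brain_truth`, `lesion_truth` (binary masks), `true_lesion_volume_mm3`,
#'   `lesions` (data frame of sphere centres in mm and radii),
#'   `injected_transform` (the [rigid2d()] applied to FLAIR),
#'   `injected_bias` (the multiplicative field on the aligned grid), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(), max_retries = 200) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$dim; sp <- spec$spacing
    co <- coord_arrays(d, sp)
    center <- d * sp / 2
    ax <- spec$brain_semiaxes

    brain <- ellipsoid_field(co, center, ax) <= 1
    outer <- ellipsoid_field(co, center, ax + spec$skull_thickness) <= 1
    skull <- outer & !brain

    # lesions: spheres placed fully inside the brain ellipsoid (conservative
    # containment bound on the sphere's extremal point)
    n_les <- if (diff(spec$lesion_count_range) == 0) spec$lesion_count_range[1] else
      sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1)
    lesion <- array(FALSE, d)
    lesion_table <- data.frame(cx = numeric(0), cy = numeric(0),
                               cz = numeric(0), r = numeric(0))
    if (n_les > 0) {
      for (l in seq_len(n_les)) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          r <- stats::runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
          cand <- center + (2 * stats::runif(3) - 1) * ax
          rel <- (abs(cand - center) + r) / ax
          if (sum(rel^2) <= 1) {
            lesion <- lesion | ((co$x - cand[1])^2 + (co$y - cand[2])^2 +
                                (co$z - cand[3])^2 <= r^2)
            lesion_table[nrow(lesion_table) + 1L, ] <- c(cand, r)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place a lesion of the requested size inside the brain")
      }
      lesion <- lesion & brain
    }

    paint <- function(int) {
      img <- array(int[["background"]], d)
      img[skull] <- int[["skull"]]
      img[brain] <- int[["brain"]]
      img[lesion] <- int[["lesion"]]
      img
    }
    t1_clean <- paint(spec$t1_intensity)
    flair_clean <- paint(spec$flair_intensity)

    bias <- injected_bias_field(spec, co, center)

    tr <- rigid2d(stats::runif(1, -1, 1) * spec$misalign_max_shift,
                  stats::runif(1, -1, 1) * spec$misalign_max_shift,
                  stats::runif(1, -1, 1) * spec$misalign_max_theta)

    t1 <- volume(t1_clean * bias + stats::rnorm(prod(d), 0, spec$noise_sigma), sp)
    flair_aligned <- volume(flair_clean * bias, sp)
    flair_moved <- if (spec$misalign_max_shift > 0 || spec$misalign_max_theta > 0)
      apply_transform(flair_aligned, tr, "spline") else flair_aligned
    flair <- volume(flair_moved$data + stats::rnorm(prod(d), 0, spec$noise_sigma), sp)

    brain_truth <- as_binary_mask(volume(array(as.numeric(brain), d), sp))
    lesion_truth <- as_binary_mask(volume(array(as.numeric(lesion), d), sp))

    structure(list(
      t1 = t1, flair = flair,
      brain_truth = brain_truth, lesion_truth = lesion_truth,
      true_lesion_volume_mm3 = lesion_volume(lesion_truth),
      lesions = lesion_table,
      injected_transform = tr,
      injected_bias = volume(bias, sp),
      spec = spec), class = "phantom_case")
  })
}

#' Generate a reproducible phantom cohort
#'
#' @param n Number of cases (>= 1).
#' @param spec A [phantom_spec()] shared by all cases; each case gets a
#'   distinct derived seed.
#' @param seed Cohort seed.
#' @return List of `n` `phantom_case` objects.
#' @export
make_dataset <- function(n, spec = phantom_spec(), seed = 1L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647)
    make_phantom(s)
  })
}
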