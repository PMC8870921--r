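#' Anisotropic diffusion settings
#'
#' Parameters of the slice-wise Perona-Malik filter used for edge-preserving
#' denoising: the diffusion coefficient decreases with local gradient
#' magnitude, so smoothing acts within tissue regions rather than across their
#' boundaries.
#'
#' @param iterations Number of explicit time steps (default 10).
#' @param kappa Conductance scale, in intensity units of the image being
#'   filtered (default 15, suited to intensities on a 0-100-ish scale; scale
#'   it down for `[0,1]` images).
#' @param dt Time step of the explicit scheme, in `(0, 0.25]` (the 2D
#'   stability bound); default 0.125.
#' @param conductance `"exponential"` (`g = exp(-(|g|/kappa)^2)`, favours
#'   high-contrast edges) or `"rational"` (`g = 1/(1+(|g|/kappa)^2)`).
#' @return A `diffusion_config` list.
#' @export
diffusion_config <- function(iterations = 10, kappa = 15, dt = 0.125,
                             conductance = c("exponential", "rational")) {
  conductance <- match.arg(conductance)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.finite(dt) || dt <= 0 || dt > 0.25)
    stop("dt must lie in (0, 0.25] for stability of the explicit scheme")
  structure(list(iterations = iterations, kappa = kappa, dt = dt,
                 conductance = conductance), class = "diffusion_config")
}

pm_conductance <- function(grad, kappa, type) {
  if (type == "exponential") exp(-(grad / kappa)^2) else 1 / (1 + (grad / kappa)^2)
}

#' Slice-wise Perona-Malik anisotropic diffusion
#'
#' Explicit 4-neighbour scheme on each axial slice with replicated-edge
#' (Neumann) boundary, so the total intensity of every slice is conserved.
#' Fluxes between neighbouring pixels are antisymmetric by construction.
#'
#' @param v A `volume`.
#' @param cfg A [diffusion_config()].
#' @return The denoised `volume`.
#' @export
anisotropic_diffuse <- function(v, cfg = diffusion_config()) {
  stopifnot_volume(v)
  if (!inherits(cfg, "diffusion_config")) stop("cfg must be a diffusion_config")
  d <- dim(v$data)
  out <- v$data
  for (k in seq_len(d[3])) {
    s <- out[, , k]
    for (it in seq_len(cfg$iterations)) {
      # neighbour differences with replicated edges (zero difference at border)
      dn <- rbind(s[-1, , drop = FALSE], s[d[1], , drop = FALSE]) - s   # +row
      ds <- rbind(s[1, , drop = FALSE], s[-d[1], , drop = FALSE]) - s   # -row
      de <- cbind(s[, -1, drop = FALSE], s[, d[2], drop = FALSE]) - s   # +col
      dw <- cbind(s[, 1, drop = FALSE], s[, -d[2], drop = FALSE]) - s   # -col
      s <- s + cfg$dt * (pm_conductance(abs(dn), cfg$kappa, cfg$conductance) * dn +
                         pm_conductance(abs(ds), cfg$kappa, cfg$conductance) * ds +
                         pm_conductance(abs(de), cfg$kappa, cfg$conductance) * de +
                         pm_conductance(abs(dw), cfg$kappa, cfg$conductance) * dw)
    }
    out[, , k] <- s
  }
  volume(out, v$spacing)
}

#' Slice-wise z-score normalization
#'
#' Each axial slice is centred on its mean and scaled by its standard
#' deviation (population SD, i.e. divisor `n`). Constant slices - typically
#' background-only edge slices - are mapped to all zeros with a warning rather
#' than raising an error.
#'
#' @param v A `volume`.
#' @return A `volume` whose non-degenerate slices have mean 0 and SD 1.
#' @export
zscore_normalize <- function(v) {
  stopifnot_volume(v)
  d <- dim(v$data)
  out <- v$data
  flat <- integer(0)
  for (k in seq_len(d[3])) {
    s <- out[, , k]
    mu <- mean(s)
    sd_pop <- sqrt(mean((s - mu)^2))
    if (sd_pop == 0) {
      out[, , k] <- 0
      flat <- c(flat, k)
    } else {
      out[, , k] <- (s - mu) / sd_pop
    }
  }
  if (length(flat))
    warning("constant slice(s) ", paste(flat, collapse = ", "),
            " set to zero during z-score normalization")
  volume(out, v$spacing)
}

#' Min-max rescale to [0, 1]
#'
#' Affine rescale of the whole volume so its minimum maps to 0 and maximum to
#' 1 (network inputs are trained on this scale). A constant volume becomes all
#' zeros with a warning.
#'
#' @param v A `volume`.
#' @return A `volume` with values in `[0, 1]`.
#' @export
minmax_rescale <- function(v) {
  stopifnot_volume(v)
  lo <- min(v$data); hi <- max(v$data)
  if (hi == lo) {
    warning("constant volume: min-max rescale returns all zeros")
    return(volume(array(0, dim(v$data)), v$spacing))
  }
  volume((v$data - lo) / (hi - lo), v$spacing)
}

#' Zero out voxels outside a brain mask
#'
#' Skull-stripping by mask transfer: the brain mask predicted on T1-w is
#' applied to both modalities.
#'
#' @param v A `volume`.
#' @param brain A binary `volume` of the same shape.
#' @return The masked `volume`.
#' @export
apply_mask <- function(v, brain) {
  stopifnot_volume(v); stopifnot_volume(brain, "brain")
  if (!identical(dim(v$data), dim(brain$data)))
    stop("volume and mask shapes differ")
  if (!is_binary_data(brain$data)) stop("brain mask must be binary")
  volume(v$data * brain$data, v$spacing)
}

poly_basis3 <- function(coords, order) {
  terms <- list(rep(1, nrow(coords)))
  for (a in 0:order) for (b in 0:(order - a)) for (cc in 0:(order - a - b)) {
    if (a + b + cc == 0) next
    terms[[length(terms) + 1L]] <-
      coords[, 1]^a * coords[, 2]^b * coords[, 3]^cc
  }
  do.call(cbind, terms)
}

#' Estimate a smooth multiplicative bias field
#'
#' Models the intensity inhomogeneity of the scanner's magnetic field as a
#' smooth multiplicative field: a low-order 3D polynomial is fitted to the log
#' intensities inside the brain mask and exponentiated, giving a strictly
#' positive field normalized to mean 1 over the mask. An adapter point for a
#' full B-spline N4 fit exists in the pipeline config, but the polynomial
#' surface is self-contained and sufficient for slowly varying fields.
#'
#' @param v A `volume` (intensities inside the mask should be positive; a
#'   shift is applied internally otherwise).
#' @param brain A non-empty binary mask `volume`.
#' @param order Polynomial order of the surface (default 3).
#' @param robust Refit after trimming voxels with large residuals (default
#'   `TRUE`). Focal structure such as lesions would otherwise inflate the
#'   field locally and be dimmed by the subsequent division; trimming keeps
#'   the fit anchored to the smooth tissue background.
#' @return A strictly positive `volume`, the estimated field, with mean 1 over
#'   the mask.
#' @export
estimate_bias_field <- function(v, brain, order = 3, robust = TRUE) {
  stopifnot_volume(v); stopifnot_volume(brain, "brain")
  if (!identical(dim(v$data), dim(brain$data)))
    stop("volume and mask shapes differ")
  idx <- which(brain$data == 1)
  if (length(idx) == 0L) stop("empty brain mask")
  d <- dim(v$data)
  vals <- v$data[idx]
  shift <- 0
  if (min(vals) <= 0) shift <- 1e-4 - min(vals)
  # voxel coordinates scaled to [-1, 1] per axis
  scale_axis <- function(i, n) if (n > 1) 2 * (i - 1) / (n - 1) - 1 else 0 * i
  ijk <- arrayInd(idx, d)
  coords <- cbind(scale_axis(ijk[, 1], d[1]), scale_axis(ijk[, 2], d[2]),
                  scale_axis(ijk[, 3], d[3]))
  X <- poly_basis3(coords, order)
  lv <- log(vals + shift)
  fit <- stats::lm.fit(X, lv)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  if (robust) {
    for (pass in 1:2) {
      resid <- lv - drop(X %*% beta)
      s <- stats::mad(resid)
      if (s == 0) break
      keep <- abs(resid) <= 2.5 * s
      if (sum(keep) < 10 * ncol(X) || all(keep)) break
      beta <- stats::lm.fit(X[keep, , drop = FALSE], lv[keep])$coefficients
      beta[is.na(beta)] <- 0
    }
  }
  all_ijk <- arrayInd(seq_len(prod(d)), d)
  all_coords <- cbind(scale_axis(all_ijk[, 1], d[1]),
                      scale_axis(all_ijk[, 2], d[2]),
                      scale_axis(all_ijk[, 3], d[3]))
  field <- exp(poly_basis3(all_coords, order) %*% beta)
  field <- array(field, d)
  field <- field / mean(field[idx])
  volume(field, v$spacing)
}

#' Divide out a multiplicative bias field
#'
#' @param v A `volume`.
#' @param field A strictly positive `volume` of the same shape (from
#'   [estimate_bias_field()]).
#' @return The corrected `volume` `v / field`.
#' @export
correct_bias <- function(v, field) {
  stopifnot_volume(v); stopifnot_volume(field, "field")
  if (!identical(dim(v$data), dim(field$data)))
    stop("volume and field shapes differ")
  if (min(field$data) <= 0) stop("bias field must be strictly positive")
  volume(v$data / field$data, v$spacing)
}
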