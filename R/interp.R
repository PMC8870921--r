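#' In-plane rigid transform
#'
#' A rigid map of in-plane (axial) physical coordinates, used to align FLAIR
#' slices with T1-w slices: rotation by `theta` about the image centre followed
#' by a translation in millimetres. As used by [apply_transform()] the map acts
#' as a pull-back: output voxel at physical position `p` (relative to the slice
#' centre) takes the input value at `R(theta) %*% p + c(tx, ty)`.
#'
#' @param tx,ty Translation in mm along the first and second array axes.
#' @param theta Rotation in radians; wrapped to `(-pi, pi]`.
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(tx = 0, ty = 0, theta = 0) {
  th <- ((theta + pi) %% (2 * pi)) - pi
  if (th == -pi) th <- pi
  structure(list(tx = as.numeric(tx), ty = as.numeric(ty), theta = th),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d tx=%.4g mm, ty=%.4g mm, theta=%.5g rad>\n",
              x$tx, x$ty, x$theta))
  invisible(x)
}

#' Compose two in-plane rigid transforms
#'
#' `rigid_compose(a, b)` is the map `p -> a(b(p))`, so applying the composite
#' with [apply_transform()] equals applying `b` then `a` in sequence.
#'
#' @param a,b `rigid2d` objects.
#' @return A `rigid2d`.
#' @export
rigid_compose <- function(a, b) {
  ca <- cos(a$theta); sa <- sin(a$theta)
  rigid2d(tx = ca * b$tx - sa * b$ty + a$tx,
          ty = sa * b$tx + ca * b$ty + a$ty,
          theta = a$theta + b$theta)
}

#' Invert an in-plane rigid transform
#' @param t A `rigid2d`.
#' @return The `rigid2d` inverse: composing the two yields the identity.
#' @export
rigid_inverse <- function(t) {
  ct <- cos(t$theta); st <- sin(t$theta)
  # inverse of p -> R p + t is p -> R^T (p - t)
  rigid2d(tx = -(ct * t$tx + st * t$ty),
          ty = -(-st * t$tx + ct * t$ty),
          theta = -t$theta)
}

interp_code <- function(interpolation) {
  switch(match.arg(interpolation, c("spline", "nearest")),
         spline = 2L, nearest = 0L)
}

# Resample onto a new regular grid with voxel-centre alignment: physical
# extent n*s is preserved, voxel i (0-based) sits at (i + 0.5) * s.
resample_grid <- function(v, newdim, newspacing, interpolation = "spline") {
  olddim <- dim(v$data)
  code <- interp_code(interpolation)
  ax <- function(k) {
    (seq_len(newdim[k]) - 0.5) * newspacing[k] / v$spacing[k] - 0.5
  }
  xi <- ax(1); yi <- ax(2); zi <- ax(3)
  g <- expand.grid(x = xi, y = yi, z = zi, KEEP.OUT.ATTRS = FALSE)
  out <- cpp_sample3(as.numeric(v$data), as.integer(olddim),
                     g$x, g$y, g$z, code)
  volume(array(out, newdim), newspacing)
}

#' Reslice a volume to a target (typically isotropic) resolution
#'
#' Resamples onto a grid at the target spacing, preserving the physical extent
#' to within one voxel per axis. Images use cubic interpolation; pass
#' `interpolation = "nearest"` for masks so they remain binary.
#'
#' @param v A `volume`.
#' @param target Length-3 target spacing in mm (default `c(1, 1, 1)`, the
#'   1 mm^3 working resolution of the pipeline).
#' @param interpolation `"spline"` (cubic, for images) or `"nearest"` (masks).
#' @return A `volume` with `spacing == target`.
#' @examples
#' v <- volume(array(rnorm(100 * 100 * 20), c(100, 100, 20)),
#'             spacing = c(0.43, 0.43, 4.6))
#' dim(reslice_isotropic(v)$data)  # 43 x 43 x 92
#' @export
reslice_isotropic <- function(v, target = c(1, 1, 1),
                              interpolation = c("spline", "nearest")) {
  stopifnot_volume(v)
  interpolation <- match.arg(interpolation)
  target <- as.numeric(target)
  if (length(target) != 3L || any(!is.finite(target)) || any(target <= 0))
    stop("degenerate target spacing: all components must be > 0")
  olddim <- dim(v$data)
  newdim <- pmax(1L, as.integer(round(olddim * v$spacing / target)))
  resample_grid(v, newdim, target, interpolation)
}

#' Resize every slice to a fixed in-plane shape
#'
#' Resamples each axial slice to `size[1] x size[2]` (the networks take
#' fixed-shape inputs); in-plane spacing is rescaled so the physical extent is
#' preserved. Slice count and through-plane spacing are untouched.
#'
#' @param v A `volume`.
#' @param size Integer `(rows, cols)`, e.g. `c(256, 256)`.
#' @param interpolation `"spline"` for images, `"nearest"` for masks.
#' @return A `volume` with in-plane shape `size`.
#' @export
resize_inplane <- function(v, size, interpolation = c("spline", "nearest")) {
  stopifnot_volume(v)
  interpolation <- match.arg(interpolation)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L)) stop("size must be two positive integers")
  olddim <- dim(v$data)
  newdim <- c(size, olddim[3])
  newspacing <- c(v$spacing[1:2] * olddim[1:2] / size, v$spacing[3])
  resample_grid(v, newdim, newspacing, interpolation)
}

#' Apply an in-plane rigid transform to every slice
#'
#' Each axial slice is resampled under the pull-back map of `t`: the output at
#' in-plane physical position `p` (mm, relative to the slice centre) is the
#' input at `R(theta) p + (tx, ty)`. Edge values are replicated.
#'
#' @param v A `volume`.
#' @param t A [rigid2d()] transform.
#' @param interpolation `"spline"` for images, `"nearest"` for masks.
#' @return The resampled `volume` (same grid and spacing).
#' @export
apply_transform <- function(v, t, interpolation = c("spline", "nearest")) {
  stopifnot_volume(v)
  if (!inherits(t, "rigid2d")) stop("t must be a rigid2d transform")
  interpolation <- match.arg(interpolation)
  code <- interp_code(interpolation)
  d <- dim(v$data)
  sx <- v$spacing[1]; sy <- v$spacing[2]
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  ij <- expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                    KEEP.OUT.ATTRS = FALSE)
  u <- (ij$i - cx) * sx
  w <- (ij$j - cy) * sy
  ct <- cos(t$theta); st <- sin(t$theta)
  xs <- (ct * u - st * w + t$tx) / sx + cx
  ys <- (st * u + ct * w + t$ty) / sy + cy
  nxy <- d[1] * d[2]
  xi <- rep(xs, d[3]); yi <- rep(ys, d[3])
  zi <- rep(seq_len(d[3]) - 1, each = nxy)
  out <- cpp_sample3(as.numeric(v$data), as.integer(d), xi, yi, zi, code)
  volume(array(out, d), v$spacing)
}
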