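#' @useDynLib lesionquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a 3D volume
#'
#' A `volume` is the carrier type for every image stage of the pipeline: a 3D
#' scalar array (in-plane axial rows x cols first, slice index last) plus the
#' voxel spacing in millimetres.
#'
#' @param data Numeric 3D array (rows x cols x slices).
#' @param spacing Numeric length-3 vector `(sx, sy, sz)` in mm, all positive.
#' @return An object of class `volume` (a list with elements `data`,
#'   `spacing`).
#' @examples
#' v <- volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 1))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array (got ",
         paste(dim(data), collapse = "x"), ")")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (any(!is.finite(data)))
    stop("volume contains non-finite voxels")
  if (dim(data)[3] < 1L) stop("volume must have at least one slice")
  structure(list(data = data, spacing = spacing), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume %dx%dx%d, spacing %.4g x %.4g x %.4g mm, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

stopifnot_volume <- function(x, what = "input") {
  if (!is_volume(x)) stop(what, " must be a volume object")
  invisible(x)
}

#' Coerce a volume to a binary mask
#'
#' Snaps voxel values to `{0, 1}`. Used when loading manual annotations whose
#' on-disk representation may carry interpolation or quantisation dust.
#'
#' @param v A `volume` whose voxels are all within `tol` of 0 or 1.
#' @param tol Maximum allowed deviation from 0 or 1 (default `1e-3`).
#' @return A `volume` whose data is exactly 0/1, additionally classed
#'   `binary_mask`.
#' @export
as_binary_mask <- function(v, tol = 1e-3) {
  stopifnot_volume(v)
  d <- v$data
  off <- pmin(abs(d), abs(d - 1))
  if (any(off > tol))
    stop(sprintf("mask has %d voxels farther than tol=%g from {0,1} (max deviation %g)",
                 sum(off > tol), tol, max(off)))
  d[] <- as.numeric(d >= 0.5)
  out <- volume(d, v$spacing)
  class(out) <- c("binary_mask", class(out))
  out
}

is_binary_data <- function(d) all(d == 0 | d == 1)

#' Coerce a volume to a probability map
#'
#' Validates that all voxels lie in `[0, 1]` (per-voxel membership values as
#' produced by the segmentation networks before thresholding).
#'
#' @param v A `volume`.
#' @return The volume, additionally classed `probability_map`.
#' @export
as_probability_map <- function(v) {
  stopifnot_volume(v)
  if (min(v$data) < 0 || max(v$data) > 1)
    stop("probability map values must lie in [0,1]")
  class(v) <- unique(c("probability_map", class(v)))
  v
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file, reorients the array so that the third index is the
#' slice axis of a canonical axial ordering (when orientation information is
#' present), and returns a [volume()] with spacing taken from the header
#' `pixdim` fields.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  # canonical axial ordering: left-right, posterior-anterior in plane,
  # inferior-superior as the slice axis
  hdr <- RNifti::niftiHeader(img)
  if (isTRUE(hdr$qform_code > 0 || hdr$sform_code > 0))
    RNifti::orientation(img) <- "RAS"
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), d)
  } else {
    stop("non-3D image: file has ", length(d), " dimensions")
  }
  if (any(!is.finite(img2))) stop("volume contains non-finite voxels: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  volume(img2, sp)
}

#' Write a volume to NIfTI
#'
#' Round-trips with [read_volume()]: data and spacing are preserved. Binary
#' masks are stored as unsigned 8-bit, images as 32-bit float.
#'
#' @param v A `volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot_volume(v)
  datatype <- if (is_binary_data(v$data)) "uint8" else "float"
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Total volume of a binary mask in cubic millimetres
#'
#' The quantification primitive: lesion load is the count of segmented voxels
#' multiplied by the voxel volume `sx * sy * sz`.
#'
#' @param mask A binary `volume` (values in `{0, 1}`).
#' @return Volume in mm^3 (scalar).
#' @examples
#' m <- volume(array(c(rep(1, 10), rep(0, 22)), c(4, 4, 2)), c(0.43, 0.43, 4.6))
#' lesion_volume(m)  # 10 * 0.43 * 0.43 * 4.6
#' @export
lesion_volume <- function(mask) {
  stopifnot_volume(mask)
  if (!is_binary_data(mask$data)) stop("mask must be binary (0/1)")
  sum(mask$data) * prod(mask$spacing)
}
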